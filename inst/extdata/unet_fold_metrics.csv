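fold_id,dice_all,dice_retained,iou_all,iou_retained
1,0.7824,0.8145,0.9211,0.9345
2,0.7591,0.7733,0.8935,0.9077
3,0.7763,0.7992,0.9048,0.9217
4,0.7199,0.7345,0.8887,0.9066
5,0.7549,0.7861,0.8994,0.9091
6,0.7688,0.7819,0.9042,0.9244
7,0.7894,0.8037,0.9178,0.9317
8,0.7666,0.7911,0.8944,0.9112
9,0.7331,0.7658,0.8773,0.8947
10,0.7543,0.7883,0.9013,0.9176
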