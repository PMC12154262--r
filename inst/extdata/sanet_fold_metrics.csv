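fold_id,dice_all,dice_retained,iou_all,iou_retained
1,0.8776,0.9025,0.9987,0.9991
2,0.8548,0.8891,0.9988,0.9990
3,0.8728,0.9102,0.9988,0.9990
4,0.8211,0.8483,0.9984,0.9988
5,0.8693,0.8872,0.9990,0.9994
6,0.8701,0.9004,0.9987,0.9991
7,0.8978,0.9122,0.9991,0.9993
8,0.8705,0.8997,0.9987,0.9990
9,0.8480,0.8739,0.9988,0.9992
10,0.8682,0.8943,0.9987,0.9991
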