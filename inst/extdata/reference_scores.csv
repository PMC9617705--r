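category,method,accuracy_pct,jsi,dsc
fibrosis,fcm,96.76,0.8839,0.9384
fibrosis,kmeans,96.97,0.8907,0.9422
fibrosis,fused,99.14,0.9686,0.9841
ground_glass,fcm,96.27,0.9126,0.9543
ground_glass,kmeans,96.74,0.9237,0.9603
ground_glass,fused,99.42,0.9862,0.993
consolidation,fcm,95.74,0.884,0.9385
consolidation,kmeans,95.98,0.8908,0.9423
consolidation,fused,99.20,0.9779,0.9888
micronodules,fcm,96.77,0.882,0.9373
micronodules,kmeans,97.28,0.8997,0.9472
micronodules,fused,99.13,0.9674,0.9834
healthy,fcm,96.79,0.9042,0.9497
healthy,kmeans,97.04,0.911,0.9534
healthy,fused,99.38,0.9813,0.9906
emphysema,fcm,97.23,0.9035,0.9493
emphysema,kmeans,97.48,0.9119,0.9539
emphysema,fused,99.42,0.9795,0.9896
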