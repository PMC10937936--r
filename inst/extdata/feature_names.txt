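# vowelpap feature manifest v1 (fixed reporting order)
pitch_mean
pitch_sd
F1
F2
F3
band_power_b100_3000
band_power_b100_500
band_power_b500_1000
band_power_b1000_1500
band_power_b1500_2000
band_power_b2000_2500
band_power_b2500_3000
band_power_b100_1000
band_power_b1000_2000
band_power_b2000_3000
relative_power_b100_3000
relative_power_b100_500
relative_power_b500_1000
relative_power_b1000_1500
relative_power_b1500_2000
relative_power_b2000_2500
relative_power_b2500_3000
relative_power_b100_1000
relative_power_b1000_2000
relative_power_b2000_3000
spectral_centroid_b100_3000
spectral_centroid_b100_500
spectral_centroid_b500_1000
spectral_centroid_b1000_1500
spectral_centroid_b1500_2000
spectral_centroid_b2000_2500
spectral_centroid_b2500_3000
spectral_centroid_b100_1000
spectral_centroid_b1000_2000
spectral_centroid_b2000_3000
mfcc_mean_1
mfcc_mean_2
mfcc_mean_3
mfcc_mean_4
mfcc_mean_5
mfcc_mean_6
mfcc_mean_7
mfcc_mean_8
mfcc_mean_9
mfcc_mean_10
mfcc_mean_11
mfcc_mean_12
mfcc_mean_13
mfcc_sd_1
mfcc_sd_2
mfcc_sd_3
mfcc_sd_4
mfcc_sd_5
mfcc_sd_6
mfcc_sd_7
mfcc_sd_8
mfcc_sd_9
mfcc_sd_10
mfcc_sd_11
mfcc_sd_12
mfcc_sd_13
chroma_mean_1
chroma_mean_2
chroma_mean_3
chroma_mean_4
chroma_mean_5
chroma_mean_6
chroma_mean_7
chroma_mean_8
chroma_mean_9
chroma_mean_10
chroma_mean_11
chroma_mean_12
chroma_sd_1
chroma_sd_2
chroma_sd_3
chroma_sd_4
chroma_sd_5
chroma_sd_6
chroma_sd_7
chroma_sd_8
chroma_sd_9
chroma_sd_10
chroma_sd_11
chroma_sd_12
contrast_mean_1
contrast_mean_2
contrast_mean_3
contrast_mean_4
contrast_mean_5
contrast_mean_6
contrast_mean_7
contrast_sd_1
contrast_sd_2
contrast_sd_3
contrast_sd_4
contrast_sd_5
contrast_sd_6
contrast_sd_7
rolloff_mean
rolloff_sd
zcr_mean
zcr_sd
spectral_skewness
spectral_kurtosis
spectral_entropy
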