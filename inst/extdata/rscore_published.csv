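feature_id,coefficient
MASK|N|morph|volume,-0.047
MASK|N|morph|flatness,-0.075
AP|N|firstorder|maximum,-0.027
AP|N|firstorder|percentile25,-0.196
AP|LOG|firstorder|median,0.049
AP|LOG|firstorder|robust_mad,-0.069
AP|N|glcm|cluster_shade,0.085
AP|N|glcm|difference_entropy,-0.106
AP|N|glcm|joint_entropy,0.656
AP|N|glszm|large_zone_high_gray_level_emphasis,0.104
AP|LOG|glcm|cluster_shade,0.251
AP|LOG|glcm|contrast,0.028
AP|LOG|glszm|zone_size_variance,-0.013
AP|G|gldzm|large_distance_high_gray_level_emphasis,0.116
AP|LOG|ngldm|high_dependence_high_gray_level_emphasis,-0.112
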