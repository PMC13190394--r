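# Simulated critical values of the truncated CIPS statistic under
# independent random walks (100,000 replicates per (N, T) grid node,
# CADF regressions with p = 0 and cross-sectional averages included).
# Regenerate with scratch/gen_cips_cv.R.
cips_cv_table <- data.frame(
  case = c("constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend", "constant_trend"),
  N = c(10, 15, 20, 27, 30, 50, 10, 15, 20, 27, 30, 50, 10, 15, 20, 27, 30, 50, 10, 15, 20, 27, 30, 50, 10, 15, 20, 27, 30, 50, 10, 15, 20, 27, 30, 50, 10, 15, 20, 27, 30, 50, 10, 15, 20, 27, 30, 50),
  T = c(15, 15, 15, 15, 15, 15, 21, 21, 21, 21, 21, 21, 30, 30, 30, 30, 30, 30, 50, 50, 50, 50, 50, 50, 15, 15, 15, 15, 15, 15, 21, 21, 21, 21, 21, 21, 30, 30, 30, 30, 30, 30, 50, 50, 50, 50, 50, 50),
  cv01 = c(-2.6622, -2.5063, -2.4303, -2.3619, -2.3403, -2.2568, -2.6037, -2.4673, -2.3903, -2.3320, -2.3105, -2.2398, -2.5784, -2.4419, -2.3781, -2.3170, -2.3021, -2.2287, -2.5540, -2.4377, -2.3719, -2.3083, -2.2925, -2.2305, -3.2275, -3.0678, -2.9723, -2.9035, -2.8882, -2.8002, -3.1402, -2.9889, -2.9152, -2.8469, -2.8254, -2.7518, -3.0853, -2.9522, -2.8841, -2.8269, -2.8050, -2.7283, -3.0560, -2.9309, -2.8630, -2.8034, -2.7855, -2.7164),
  cv05 = c(-2.3753, -2.2746, -2.2186, -2.1736, -2.1651, -2.1112, -2.3468, -2.2580, -2.2041, -2.1617, -2.1516, -2.1057, -2.3350, -2.2474, -2.2051, -2.1640, -2.1514, -2.1071, -2.3287, -2.2476, -2.2066, -2.1633, -2.1535, -2.1128, -2.9220, -2.8215, -2.7553, -2.7066, -2.6966, -2.6339, -2.8740, -2.7819, -2.7277, -2.6829, -2.6669, -2.6156, -2.8542, -2.7619, -2.7130, -2.6725, -2.6575, -2.6085, -2.8419, -2.7551, -2.7068, -2.6666, -2.6554, -2.6076),
  cv10 = c(-2.2253, -2.1493, -2.1089, -2.0760, -2.0664, -2.0277, -2.2116, -2.1445, -2.1034, -2.0719, -2.0645, -2.0312, -2.2077, -2.1407, -2.1099, -2.0782, -2.0690, -2.0358, -2.2086, -2.1458, -2.1144, -2.0827, -2.0738, -2.0439, -2.7643, -2.6889, -2.6400, -2.6034, -2.5953, -2.5488, -2.7366, -2.6679, -2.6289, -2.5932, -2.5827, -2.5425, -2.7334, -2.6603, -2.6238, -2.5932, -2.5789, -2.5431, -2.7296, -2.6618, -2.6242, -2.5926, -2.5833, -2.5457)
)
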