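blue,red,white,far_red,sucrose,mean_shoot_length,se_shoot_length,mean_root_length,se_root_length,mean_node_number,se_node_number,mean_shoot_number,se_shoot_number,mean_canopy_area,se_canopy_area,n
25,0,25,0,1,38.77,8.101,108.87,10.097,8.5,0.645,1,0,2309.42,314.907,4
25,0,25,0,3,32.44,7.036,42.47,29.857,8,0.408,2.25,0.479,2028.24,598.38,4
25,0,25,0,6,63.26,16.667,117.06,20.197,8,0.408,2.25,0.479,1885.75,385.882,4
50,0,0,0,1,32.94,2.406,26.45,23.515,7.25,0.75,1,0,1848.11,214.644,4
50,0,0,0,3,44.35,20.174,24.56,15.198,7.25,1.601,1.5,0.5,1495.87,757.315,4
50,0,0,0,6,39.03,10.839,142.17,45.483,7.5,0.866,1.25,0.25,1589.48,578.975,4
50,0,50,0,1,31.2,5.443,151.4,35.982,8.25,0.629,1,0,1717.8,582.898,4
50,0,50,0,3,40.91,13.542,82.77,17.954,8.5,0.5,1.25,0.25,1802.86,390.86,4
50,0,50,0,6,53.83,13.807,112.46,26.505,9,0.707,1.75,0.479,1880.05,744.967,4
100,0,0,0,1,23.43,2.634,0,0,5.75,0.479,1.25,0.25,493.01,111.615,4
100,0,0,0,3,22.95,2.991,15.04,8.855,6.75,0.479,1,0,650.45,126.813,4
100,0,0,0,6,33.42,11.272,102.47,60.796,6.5,0.5,2,0.577,890.63,444.374,4
12.5,12.5,12.5,12.5,1,43.13,9.839,97.61,34.009,7.25,0.479,1.5,0.289,2442.35,506.213,4
12.5,12.5,12.5,12.5,3,59.6,10.319,89.45,31.042,7.75,0.854,1.75,0.25,3193.41,888.482,4
12.5,12.5,12.5,12.5,6,64.51,38.597,63.48,34.099,8.25,2.016,1.75,0.479,2594.11,1648.261,4
37.5,12.5,0,0,1,47.4,11.309,63.68,24.567,7,0.816,1.5,0.289,1519.41,345.197,4
37.5,12.5,0,0,3,66.39,16.88,136.61,28.052,8,1.08,2.25,0.629,2177.63,519.451,4
37.5,12.5,0,0,6,38.41,5.652,100.51,37.32,7.75,0.479,1.5,0.289,1698.48,448.503,4
16.69,16.69,0,16.69,1,106.24,35.988,127.38,40.798,8,0.707,1.25,0.25,3350.76,789.191,4
16.69,16.69,0,16.69,3,142.22,36.056,101.97,41.471,9.75,0.75,2.5,0.866,4355.61,1395.277,4
16.69,16.69,0,16.69,6,38.89,11.084,46.67,29.388,6.75,0.854,1.25,0.25,1360.77,155.798,4
25,25,0,0,1,57.72,14.566,149.92,35.873,8.75,1.181,1,0,3776.96,1017.968,4
25,25,0,0,3,56.83,32.88,105.16,44.817,7.5,0.645,1.75,0.25,1737.36,1056.285,4
25,25,0,0,6,61.38,9.666,38.72,23.529,8.25,0.946,2,0.408,1216.37,114.887,4
25,25,25,25,1,87.11,22.707,134.47,48.218,8.75,0.854,1.75,0.25,6340.05,1284.607,4
25,25,25,25,3,56.06,12.648,72.8,36.452,9.25,0.25,1,0,3117.44,887.353,4
25,25,25,25,6,59.93,24.137,146,54.432,7,0.707,1.25,0.25,1829.2,645.785,4
75,25,0,0,1,33.3,5.883,65.71,42.275,7.5,1.041,1,0,2560.02,620.724,4
75,25,0,0,3,103.74,44.839,112.05,16.975,10.5,2.021,2,0.408,3964.16,1336.336,4
75,25,0,0,6,41.43,1.379,29.16,13.225,7.5,0.645,1.25,0.25,813.38,188.339,4
33.33,33.33,0,33.33,1,36.42,6.816,150.89,51.445,8.75,0.854,1.25,0.25,2091.81,525.087,4
33.33,33.33,0,33.33,3,98.4,44.716,477.1,287.094,11.5,2.901,1,0,2483.71,627.011,4
33.33,33.33,0,33.33,6,85.94,16.989,147.32,7.069,9.25,0.854,1.75,0.25,7136.78,1770.492,4
12.5,37.5,0,0,1,49.05,14.862,120.84,70.678,7.75,0.854,1.25,0.25,3232.08,1237.421,4
12.5,37.5,0,0,3,32.11,3.359,10.84,10.841,7,0,2,0.408,2505.37,374.173,4
12.5,37.5,0,0,6,50.48,11.078,122.62,37.803,8.25,0.479,2.25,0.946,1992.3,318.378,4
0,50,0,0,1,77.72,11.483,97.43,36.702,8.25,0.479,1.25,0.25,2500.7,678.427,4
0,50,0,0,3,99.81,31.278,158,58.672,7.75,0.946,1.75,0.479,3148.87,1255.456,4
0,50,0,0,6,46.9,1.499,35.98,20.84,8.5,0.289,1.5,0.289,1383.03,349.575,4
50,50,0,0,1,29.51,6.815,77.13,45.344,8.5,0.866,1.25,0.25,2447.43,737.653,4
50,50,0,0,3,68.5,16.044,73.5,26.47,8.75,0.629,2.25,0.479,13061.97,10839.642,4
50,50,0,0,6,55.4,24.082,29.79,29.794,9,0.707,2,0.408,1963.27,1336.004,4
0,50,25,0,1,63.01,11.807,87.61,55.464,9,0.707,1.5,0.289,2763.95,630.766,4
0,50,25,0,3,130.47,48.757,152.19,40.475,9.75,1.181,1.25,0.25,6939.43,2672.142,4
0,50,25,0,6,91.8,61.557,132.78,92.911,9.5,1.555,1.75,0.75,3000.23,1620.64,4
0,50,50,0,1,55.39,6.538,47.25,33.256,8.5,0.866,1,0,3123.43,594.904,4
0,50,50,0,3,73.49,16.669,159.08,45.374,9.5,0.645,1.75,0.479,5721.65,2203.448,4
0,50,50,0,6,78.72,27.594,91.01,34.488,8.5,0.5,1.5,0.289,3337.97,1156.575,4
25,75,0,0,1,49.02,6.926,121.57,43.981,8.5,0.866,1,0,3843.37,1073.415,4
25,75,0,0,3,78.73,21.04,79.38,39.101,10.5,1.19,1,0,6154.32,1303.577,4
25,75,0,0,6,55.71,17.245,75.76,27.694,9,0.408,1.25,0.25,2682.36,913.655,4
0,100,0,0,1,48.72,17.838,152.42,43.433,8,0.816,1.25,0.25,1642.67,438.197,4
0,100,0,0,3,101.24,32.678,207.67,41.674,7.5,0.289,1.25,0.25,1529.03,407.505,4
0,100,0,0,6,84.14,37.295,143.37,84.434,8.25,0.854,2,0.408,915.09,717.054,4
0,0,25,25,1,76.46,34.634,160.01,49.307,7.75,0.75,1.25,0.25,2370.35,467.347,4
0,0,25,25,3,154.68,51.228,171.42,17.863,8.5,1.041,1.5,0.289,2707.43,652.476,4
0,0,25,25,6,86.78,29.794,86.57,38.613,8,0.408,1.25,0.25,2782.91,1022.655,4
0,0,50,0,1,39.5,5.238,128.04,12.026,8.5,0.289,1.25,0.25,2751.85,906.598,4
0,0,50,0,3,35.85,6.99,74.44,27.158,8.25,0.479,1.5,0.289,1706.28,611.107,4
0,0,50,0,6,82.77,43.133,72.39,41.802,8,1,1.5,0.289,2249.33,1412.72,4
0,0,50,50,1,38.61,6.648,0,0,8.75,0.479,1,0,2169.51,649.21,4
0,0,50,50,3,136.64,29.794,148.92,23.789,8.75,0.629,2,0.408,3411.27,345.452,4
0,0,50,50,6,36.78,0.374,4.4,4.396,8,0.408,1.25,0.25,859.96,78.081,4
0,0,100,0,1,27.7,2.311,4.36,4.363,7.25,0.479,1.5,0.289,519.06,182.411,4
0,0,100,0,3,39.88,3.684,9.05,5.546,8,0.707,1,0,1954.42,506.636,4
0,0,100,0,6,101.32,35.475,177.03,26.461,8,1.08,3,0.577,2593.13,526.681,4
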