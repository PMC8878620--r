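accession,citronellal,citronellol,geraniol,sd_citronellal,sd_citronellol,sd_geraniol
IC-0627004,3.745,20.433,41.146,0.098,0.021,0.058
IC-0627019,43.404,14.935,20.188,0.067,0.055,0.041
IC-0627018,42.934,11.264,22.437,0.015,0.071,0.034
IC-0627017,42.641,11.374,23.27,0.053,0.017,0.062
IC-0627016,41.843,9.862,22.323,0.067,0.048,0.056
IC-0627006,43.333,15.018,13.339,0.019,0.003,0.005
IC-0627005,42.196,11.234,18.851,0.055,0.022,0.037
IC-0627003,4.485,23,39.842,0.083,0.041,0.075
IC-0627002,5.723,26.389,31.448,0.08,0.052,0.005
IC-0626993,51.45,10.064,19.32,0.048,0.087,0.075
IC-0626991,42.501,14.311,17.301,0.063,0.014,0.042
IC-0627064,19.975,11.143,29.912,0.051,0.018,0.037
IC-0627065,46.511,13.747,19.304,0.063,0.027,0.079
IC-0627063,46.022,11.919,18.807,0.018,0.046,0.031
IC-0627062,48.477,9.245,20.48,0.057,0.061,0.028
IC-0627058,47.383,11.282,14.979,0.063,0.074,0.052
IC-0627057,46.658,10.329,20.04,0.038,0.14,0.097
IC-0627056,46.606,11.425,17.554,0.071,0.044,0.086
IC-0627052,46.287,10.728,18.898,0.083,0.052,0.029
IC-0627051,46.411,11.971,16.671,0.046,0.061,0.018
IC-0627050,42.738,12.88,20.242,0.022,0.071,0.034
IC-0627049,48.744,12.182,15.282,0.011,0.058,0.029
IC-0627048,45.785,11.419,20.443,0.042,0.03,0.057
IC-0627047,40.192,12.722,24.037,0.057,0.092,0.023
IC-0627046,41.2,8.999,21.093,0.014,0.052,0.075
IC-0627045,38.411,11.272,24.342,0.052,0.037,0.049
IC-0627044,37.405,11.925,22.823,0.043,0.062,0.057
IC-0627042,38.166,11.753,23.059,0.051,0.009,0.036
IC-0627041,40.901,11.049,18.885,0.034,0.057,0.044
IC-0627040,40.86,11.993,21.321,0.052,0.043,0.071
IC-0627039,42.306,12.591,20.396,0.049,0.027,0.052
IC-0627038,38.345,11.878,22.924,0.061,0.033,0.038
IC-0627037,43.995,13.729,22.272,0.057,0.061,0.041
IC-0627036,18.938,12.122,11.734,0.043,0.025,0.076
IC-0627033,31.997,12.288,22.196,0.062,0.059,0.071
IC-0627035,47.569,11.116,18.029,0.055,0.049,0.038
IC-0627034,35.657,10.261,24.533,0.037,0.082,0.051
IC-0627032,39.754,11.103,22.976,0.021,0.076,0.039
IC-0627031,19.057,9.474,38.826,0.069,0.048,0.082
IC-0627028,40.541,11.978,22.376,0.075,0.024,0.061
IC-0627030,46.781,13.714,20.406,0.043,0.037,0.05
IC-0627026,44.4,12.677,19.164,0.019,0.095,0.039
IC-0627027,41.479,11.134,21.566,0.038,0.042,0.017
IC-0627024,49.09,13.578,17.144,0.013,0.074,0.042
IC-0627025,38.012,10.726,22.645,0.032,0.056,0.013
IC-0627023,45.2,11.486,19.139,0.068,0.057,0.065
IC-0627022,36.825,9.661,20.483,0.024,0.049,0.039
IC-0627021,42.863,15.486,21.574,0.055,0.008,0.027
IC-0627054,43.105,14.106,18.136,0.037,0.029,0.034
IC-0627043,41.864,13.929,23.171,0.022,0.045,0.017
IC-0626995,20.119,14.112,35.834,0.039,0.017,0.045
IC-0627060,49.543,10.153,18.67,0.046,0.013,0.082
IC-0627055,44.487,11.503,12.079,0.061,0.072,0.042
IC-0626994,42.225,13.442,17.16,0.046,0.095,0.052
IC-0627059,45.059,13.2,16.611,0.074,0.024,0.059
IC-0627012,22.73,11.733,22.741,0.043,0.027,0.038
IC-0626998,43.068,9.637,21.123,0.052,0.078,0.014
IC-0627013,21.914,9.986,34.194,0.024,0.132,0.154
IC-0627001,42.346,15.29,18.762,0.092,0.014,0.043
IC-0627029,44.85,13.011,22.343,0.089,0.046,0.057
IC-0627009,2.356,0,0,0.048,NA,NA
IC-0627014,45.857,13.245,19.208,0.074,0.016,0.061
IC-0626996,45.015,12.879,19.924,0.062,0.047,0.035
IC-0626999,3.559,10.532,22.834,0.071,0.063,0.054
IC-0626997,2.703,2.682,2.967,0.083,0.075,0.073
IC-0627000,40.551,10.816,21.96,0.069,0.021,0.056
IC-0627011,21.393,9.147,38.883,0.007,0.084,0.037
IC-0627061,43.561,9.567,21.127,0.045,0.063,0.05
IC-0626992,40.386,11.145,19.42,0.037,0.029,0.01
IC-0627053,40.309,10.628,18.32,0.023,0.031,0.081
IC-0627007,38.334,11.773,20.003,0.045,0.018,0.063
IC-0627008,2.578,0,0,0.012,NA,NA
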