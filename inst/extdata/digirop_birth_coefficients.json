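{"names":["intercept","t_0_8","t_8_12","t_gt12","ga_24_27","ga_gt27","sex","bwsds_le_m1","bwsds_gt_m1","t_x_ga_24_27","t_x_ga_gt27","sex_x_ga","t_x_bwsds_le_m1","t_x_bwsds_gt_m1"],"estimates":[-20.1666,1.7331,0.3618,-0.3788,-0.821,0.7266,-0.9385,0.1521,-1.0401,0.0227,-0.136,-0.2505,-0.0371,0.0728],"ses":[4.9219,0.6129,0.0992,0.0857,0.3353,0.7302,0.3054,0.2656,0.471,0.023,0.0627,0.1066,0.0199,0.0349],"covariance":[[24.22509961,0,0,0,0,0,0,0,0,0,0,0,0,0],[0,0.37564641,0,0,0,0,0,0,0,0,0,0,0,0],[0,0,0.00984064,0,0,0,0,0,0,0,0,0,0,0],[0,0,0,0.00734449,0,0,0,0,0,0,0,0,0,0],[0,0,0,0,0.11242609,0,0,0,0,0,0,0,0,0],[0,0,0,0,0,0.53319204,0,0,0,0,0,0,0,0],[0,0,0,0,0,0,0.09326916,0,0,0,0,0,0,0],[0,0,0,0,0,0,0,0.07054336,0,0,0,0,0,0],[0,0,0,0,0,0,0,0,0.221841,0,0,0,0,0],[0,0,0,0,0,0,0,0,0,0.000529,0,0,0,0],[0,0,0,0,0,0,0,0,0,0,0.00393129,0,0,0],[0,0,0,0,0,0,0,0,0,0,0,0.01136356,0,0],[0,0,0,0,0,0,0,0,0,0,0,0,0.00039601,0],[0,0,0,0,0,0,0,0,0,0,0,0,0,0.00121801]],"covariance_synthetic":true,"encoding":{"t_knots":[8,12],"ga_knot":27,"bwsds_knot":-1,"c_ga_main":28,"c_ga_sex":28,"c_bwsds":0,"t_interaction_form":"raw"}}
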