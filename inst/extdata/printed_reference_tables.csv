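table,parameter,mean_male,sd_male,mean_female,sd_female,n_male,n_female,t_printed,total_mean_printed,total_sd_printed
inner,Screw Length,47.07,4.08,45.95,3.93,40,40,1.261,46.51,4.01
inner,MAIA,14.06,8.91,10.74,9.95,40,40,1.573,12.40,9.53
inner,MPIA,-13.30,10.72,-10.25,9.60,40,40,-1.341,-11.78,10.22
outer,Screw Length,55.71,6.36,48.68,8.65,40,40,4.139,52.19,8.33
outer,MAIA,9.77,10.53,10.94,8.33,40,40,-0.553,10.35,9.46
outer,MPIA,-11.80,11.00,-6.23,7.91,40,40,-2.599,-9.02,9.92
tangential,Screw Length,53.16,8.70,45.07,10.91,40,40,5.026,50.61,11.28
tangential,MIA,30.42,7.95,32.88,10.65,40,40,-1.167,31.65,9.42
tangential,APIA,9.32,9.57,5.74,10.58,40,40,0.117,7.53,10.18
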