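method,metric,class,scene1,scene2,scene3,scene4,scene5,scene6
sequential,tp_rate,FRUIT,76.5,67.7,77.1,58.9,61.1,68.6
sequential,tp_rate,STEM,94,88.8,85.1,84.3,78.5,66
sequential,tp_rate,LEAF,90,83.7,80.6,68.7,77,92.1
sequential,tp_rate,BRANCH,28,15,34,26.1,39.8,2.8
sequential,tp_rate,BACKGROUND,91.2,79.5,48.6,82.3,66.2,64.5
sequential,fp_rate,FRUIT,0.6,2.9,0.6,0.1,0.2,2.1
sequential,fp_rate,STEM,2.6,4.4,6.75,1.6,4.1,5.1
sequential,fp_rate,LEAF,6.9,10.5,16.8,8.5,16.8,26
sequential,fp_rate,BRANCH,4.7,7.9,15.1,21.5,15.4,2.9
sequential,fp_rate,BACKGROUND,1.5,1.8,1.8,4.9,3,2.2
sequential,precision,FRUIT,95,77.1,93.4,93.6,98,80.9
sequential,precision,STEM,72.6,58.3,42.5,61.1,57.2,51.6
sequential,precision,LEAF,93.8,89.5,80.9,96.1,86,79.2
sequential,precision,BRANCH,7.1,4.5,6.8,1,8.7,4.5
sequential,precision,BACKGROUND,95.7,94,93.2,78.4,83.4,90.6
sequential,accuracy,TOTAL,88.1,79.2,68.3,70.9,71.5,76.5
sequential,error_rate,TOTAL,11.9,20.8,31.7,29.1,28.5,23.5
rgb_baseline,precision,FRUIT,89.3,76.1,43.9,54.7,97.8,72.9
rgb_baseline,precision,STEM,12.1,11.5,2.4,5.1,18.6,9.1
rgb_baseline,precision,LEAF,77.9,65.1,5.0,93.8,84.7,19.0
rgb_baseline,precision,BRANCH,1.9,1,1.5,1.2,10.8,1.21
rgb_baseline,precision,BACKGROUND,79.1,85.4,76.8,56.8,23.7,78
rgb_baseline,accuracy,TOTAL,37.4,28.4,15.4,52.1,58.0,19.3
rgb_baseline,error_rate,TOTAL,62.6,71.6,84.6,47.8,42.0,80.7
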