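case_study,table,level,network,classifier,features,bias,mode,mean,sd
1,1,single_track,alexnet,svm,deep,NA,background_suppression,72.83,5.22
1,1,single_track,googlenet,svm,deep,NA,background_suppression,71.55,4.85
1,1,single_track,resnet101,svm,deep,NA,background_suppression,74.00,4.37
1,1,single_track,nasnetlarge,svm,deep,NA,background_suppression,74.44,4.40
1,1,cluster,alexnet,svm,deep,NA,background_suppression,70.00,7.73
1,1,cluster,googlenet,svm,deep,NA,background_suppression,79.52,7.48
1,1,cluster,resnet101,svm,deep,NA,background_suppression,80.48,6.59
1,1,cluster,nasnetlarge,svm,deep,NA,background_suppression,82.38,5.66
1,2,single_track,NA,svm,shape_texture,NA,NA,64.52,6.73
1,2,cluster,NA,svm,shape_texture,NA,NA,73.49,9.20
1,2,single_track,NA,rf,shape_texture,NA,NA,62.89,4.56
1,2,cluster,NA,rf,shape_texture,NA,NA,66.51,10.02
1,2,single_track,resnet101,rf,deep,NA,background_suppression,72.06,5.16
1,2,cluster,resnet101,rf,deep,NA,background_suppression,78.73,5.67
1,2,single_track,NA,lda,shape_texture,NA,NA,66.96,11.18
1,2,cluster,NA,lda,shape_texture,NA,NA,66.51,12.31
1,2,single_track,resnet101,lda,deep,NA,background_suppression,73.36,6.77
1,2,cluster,resnet101,lda,deep,NA,background_suppression,76.35,8.15
1,2,single_track,NA,knn,shape_texture,NA,NA,61.11,7.98
1,2,cluster,NA,knn,shape_texture,NA,NA,70.63,6.36
1,2,single_track,resnet101,knn,deep,NA,background_suppression,68.49,6.36
1,2,cluster,resnet101,knn,deep,NA,background_suppression,72.22,5.94
1,3,single_track,resnet101,svm,deep,0,no_preprocessing,79.63,3.75
1,3,single_track,resnet101,svm,deep,0,background_suppression,74.00,4.37
1,3,single_track,resnet101,svm,deep,0.3,no_preprocessing,78.22,6.91
1,3,single_track,resnet101,svm,deep,0.3,background_suppression,74.16,4.41
1,3,single_track,resnet101,svm,deep,0.5,no_preprocessing,56.92,6.47
1,3,single_track,resnet101,svm,deep,0.5,background_suppression,74.03,5.08
2,4,single_track,alexnet,svm,deep,NA,background_suppression,76.17,3.47
2,4,single_track,googlenet,svm,deep,NA,background_suppression,76.06,4.09
2,4,single_track,resnet101,svm,deep,NA,background_suppression,77.88,3.41
2,4,single_track,nasnetlarge,svm,deep,NA,background_suppression,73.70,3.80
2,4,cluster,alexnet,svm,deep,NA,background_suppression,86.77,4.64
2,4,cluster,googlenet,svm,deep,NA,background_suppression,84.42,5.36
2,4,cluster,resnet101,svm,deep,NA,background_suppression,84.03,3.73
2,4,cluster,nasnetlarge,svm,deep,NA,background_suppression,81.78,5.19
2,5,single_track,NA,svm,shape_texture,NA,NA,61.71,4.33
2,5,cluster,NA,svm,shape_texture,NA,NA,64.46,7.08
2,5,single_track,NA,rf,shape_texture,NA,NA,53.81,4.24
2,5,cluster,NA,rf,shape_texture,NA,NA,56.08,8.19
2,5,single_track,resnet101,rf,deep,NA,background_suppression,72.80,4.46
2,5,cluster,resnet101,rf,deep,NA,background_suppression,80.07,6.17
2,5,single_track,NA,lda,shape_texture,NA,NA,55.15,8.22
2,5,cluster,NA,lda,shape_texture,NA,NA,53.84,12.51
2,5,single_track,resnet101,lda,deep,NA,background_suppression,74.34,4.92
2,5,cluster,resnet101,lda,deep,NA,background_suppression,86.51,6.56
2,5,single_track,NA,knn,shape_texture,NA,NA,51.04,6.66
2,5,cluster,NA,knn,shape_texture,NA,NA,52.52,11.67
2,5,single_track,resnet101,knn,deep,NA,background_suppression,70.52,4.41
2,5,cluster,resnet101,knn,deep,NA,background_suppression,81.61,5.42
2,6,single_track,resnet101,svm,deep,0,no_preprocessing,75.55,4.09
2,6,single_track,resnet101,svm,deep,0,background_suppression,77.88,3.41
2,6,single_track,resnet101,svm,deep,0.3,no_preprocessing,65.29,5.88
2,6,single_track,resnet101,svm,deep,0.3,background_suppression,77.90,3.69
2,6,single_track,resnet101,svm,deep,0.5,no_preprocessing,49.23,8.70
2,6,single_track,resnet101,svm,deep,0.5,background_suppression,76.70,3.74
1,7,single_timepoint,resnet101,svm,deep,NA,background_suppression,64.15,0.60
1,7,single_track,resnet101,svm,deep,NA,background_suppression,74.00,4.37
1,7,cluster,resnet101,svm,deep,NA,background_suppression,80.48,6.59
2,7,single_timepoint,resnet101,svm,deep,NA,background_suppression,64.94,0.62
2,7,single_track,resnet101,svm,deep,NA,background_suppression,77.88,3.41
2,7,cluster,resnet101,svm,deep,NA,background_suppression,84.03,3.73
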