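mechanism,criterion,rank,method
MCAR,accuracy,1,forest
MCAR,accuracy,2,iterative_pca
MCAR,accuracy,3,svd
MCAR,accuracy,4,knn
MCAR,accuracy,5,mean
MCAR,accuracy,6,median
MCAR,accuracy,7,qrilc
MCAR,accuracy,8,min
MCAR,accuracy,9,half_min
MCAR,accuracy,10,random
MCAR,accuracy,11,zero
MAR,accuracy,1,iterative_pca
MAR,accuracy,2,forest
MAR,accuracy,3,svd
MAR,accuracy,4,knn
MAR,accuracy,5,mean
MAR,accuracy,6,median
MAR,accuracy,7,qrilc
MAR,accuracy,8,min
MAR,accuracy,9,half_min
MAR,accuracy,10,random
MAR,accuracy,11,zero
MNAR_LOD,accuracy,1,min
MNAR_LOD,accuracy,2,half_min
MNAR_LOD,accuracy,3,qrilc
MNAR_LOD,accuracy,4,iterative_pca
MNAR_LOD,accuracy,5,svd
MNAR_LOD,accuracy,6,forest
MNAR_LOD,accuracy,7,knn
MNAR_LOD,accuracy,8,zero
MNAR_LOD,accuracy,9,median
MNAR_LOD,accuracy,10,mean
MNAR_LOD,accuracy,11,random
overall,accuracy,1,iterative_pca
overall,accuracy,2,forest
overall,accuracy,3,svd
overall,accuracy,4,knn
overall,accuracy,5,min
overall,accuracy,6,qrilc
overall,accuracy,7,mean
overall,accuracy,8,median
overall,accuracy,9,half_min
overall,accuracy,10,random
overall,accuracy,11,zero
MCAR,speed,1,zero
MCAR,speed,2,min
MCAR,speed,3,half_min
MCAR,speed,4,mean
MCAR,speed,5,median
MCAR,speed,6,random
MCAR,speed,7,knn
MCAR,speed,8,svd
MCAR,speed,9,iterative_pca
MCAR,speed,10,qrilc
MCAR,speed,11,forest
MAR,speed,1,zero
MAR,speed,2,min
MAR,speed,3,half_min
MAR,speed,4,mean
MAR,speed,5,median
MAR,speed,6,random
MAR,speed,7,knn
MAR,speed,8,svd
MAR,speed,9,iterative_pca
MAR,speed,10,qrilc
MAR,speed,11,forest
MNAR_LOD,speed,1,zero
MNAR_LOD,speed,2,min
MNAR_LOD,speed,3,half_min
MNAR_LOD,speed,4,mean
MNAR_LOD,speed,5,median
MNAR_LOD,speed,6,random
MNAR_LOD,speed,7,qrilc
MNAR_LOD,speed,8,knn
MNAR_LOD,speed,9,svd
MNAR_LOD,speed,10,iterative_pca
MNAR_LOD,speed,11,forest
overall,speed,1,zero
overall,speed,2,min
overall,speed,3,half_min
overall,speed,4,mean
overall,speed,5,median
overall,speed,6,random
overall,speed,7,knn
overall,speed,8,svd
overall,speed,9,iterative_pca
overall,speed,10,qrilc
overall,speed,11,forest
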