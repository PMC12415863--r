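species,endpoint,architecture,hidden_activation,output_activation,trainer_name,output_bias,caveats
common_carp,IT,1-10-1,purelin,purelin,traingda,0.0162,
common_carp,RT,1-10-1,purelin,purelin,traingda,13.8936,table block is unlabeled in print; identified as RT by elimination and the narrative text
common_carp,WBC,1-6-1,purelin,purelin,trainrp,10.3895,
common_carp,RBC,1-7-1,tansig,purelin,trainsgd,-0.0054,trainsgd expands to the same adaptive-learning-rate gradient descent as traingda
common_carp,HGB,1-5-1,logsig,purelin,trains,13.8936,printed output bias 13.8936 duplicates the RT block value
common_carp,HCT,1-7-1,tansig,purelin,traingda,0.0280,"text says 1-7-1, table block has 8 rows|table block labeled RBC in print; identified as HCT by the narrative text"
danube_sturgeon,IT,1-10-1,logsig,purelin,traingda,87.513,rows 1 and 10 print the same hidden bias 124.454
danube_sturgeon,RT,1-8-1,tansig,purelin,traingda,50.091,
danube_sturgeon,WBC,1-7-1,purelin,purelin,traingda,11.457,
danube_sturgeon,RBC,1-5-1,tansig,purelin,traingda,-0.0156,
danube_sturgeon,HGB,1-7-1,purelin,purelin,trains,4.964,rows 1-5 duplicate the carp HGB block at reduced precision
danube_sturgeon,HCT,1-10-1,tansig,purelin,traingda,0.019,table block labeled RBC in print; identified as HCT by the narrative text
rainbow_trout,IT,1-8-1,tansig,purelin,trains,3.344,row i=3 absent from printed table; 7 rows vs. stated 1-8-1
rainbow_trout,RT,1-6-1,tansig,purelin,traingda,27.481,
rainbow_trout,WBC,1-5-1,purelin,purelin,traingda,0.883,
rainbow_trout,RBC,1-4-1,logsig,purelin,traingda,-0.642,
rainbow_trout,HGB,1-10-1,tansig,purelin,trains,0.064,rows 8 and 9 are printed identical
rainbow_trout,HCT,1-8-1,logsig,purelin,traingda,0.028,table block labeled RBC in print; identified as HCT by the narrative text|closely resembles the carp HCT block at reduced precision
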