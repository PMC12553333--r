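architecture,learning_rate,dropout,activation,n_heads,n_layers,hidden_dim,pooling,batch_size,max_epochs,norm,conv_filters,conv_kernels
cnn,1e-04,0.1,relu,NA,3,256,max,32,100,none,32|64|96,4|8|12
cnn_gru,1e-04,0.1,relu,NA,2,64,mean,32,100,none,32|64|96,4|8|12
transformer,1e-04,0.1,relu,4,2,64,max,32,100,layer,,
gcn,1e-05,0.1,relu,NA,3,64,weighted_sum_max,32,100,batch,,
gat,1e-05,0.1,relu,4,3,64,weighted_sum_max,32,100,none,,
mpnn,1e-05,0.1,relu,NA,6,64,sum_max,32,100,none,,
neuralfp,1e-05,0.1,relu,NA,3,64,sum_max,32,100,batch,,
attentivefp,1e-05,0.1,relu,NA,3,64,attentive,32,100,none,,
pagtn,1e-05,0.1,leaky_relu,NA,5,64,weighted_sum_max,32,100,none,,
graphormer,1e-05,0.1,relu,8,1,64,max,32,100,layer,,
fixed_embedding,1e-03,0.1,relu,NA,2,256,,32,100,none,,
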