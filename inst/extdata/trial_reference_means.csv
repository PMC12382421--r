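timepoint,outcome,mean_intervention,mean_control,averted
post1m,healthcare_costs,7658,3926,FALSE
post1m,societal_costs,23758,18265,FALSE
post1m,nssi_frequency,1.29,2.21,TRUE
post1m,nssi_remission,0.61,0.38,FALSE
post1m,qalys,0.205,0.199,FALSE
post3m,healthcare_costs,9649,6126,FALSE
post3m,societal_costs,34559,28328,FALSE
post3m,nssi_frequency,1.17,1.68,TRUE
post3m,nssi_remission,0.58,0.51,FALSE
post3m,qalys,0.313,0.302,FALSE
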