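structure_label,cell,energy
unmodified_i,A1,3.32
unmodified_i,A2,3.34
unmodified_i,A3,4.80
unmodified_i,B1,2.70
unmodified_i,B2,3.93
unmodified_i,B3,7.74
unmodified_i,C1,5.00
unmodified_i,C2,4.99
unmodified_i,C3,8.49
unmodified_ii,A1,3.97
unmodified_ii,A2,4.63
unmodified_ii,A3,7.02
unmodified_ii,B1,3.38
unmodified_ii,B2,3.88
unmodified_ii,B3,8.10
unmodified_ii,C1,5.62
unmodified_ii,C2,4.41
unmodified_ii,C3,6.78
unmodified_iii,A1,4.35
unmodified_iii,A2,3.86
unmodified_iii,A3,9.33
unmodified_iii,B1,3.81
unmodified_iii,B2,4.05
unmodified_iii,B3,9.27
unmodified_iii,C1,4.36
unmodified_iii,C2,3.75
unmodified_iii,C3,6.91
hyperacetylated_i,A1,-2.55
hyperacetylated_i,A2,-2.21
hyperacetylated_i,A3,-0.24
hyperacetylated_i,B1,-3.51
hyperacetylated_i,B2,-3.88
hyperacetylated_i,B3,-1.02
hyperacetylated_i,C1,-2.80
hyperacetylated_i,C2,-3.28
hyperacetylated_i,C3,0.28
active_i,A1,0.89
active_i,A2,0.97
active_i,A3,1.32
active_i,B1,-1.43
active_i,B2,-0.79
active_i,B3,1.93
active_i,C1,-0.26
active_i,C2,-0.12
active_i,C3,1.54
inactive_i,A1,-0.70
inactive_i,A2,-0.55
inactive_i,A3,0.75
inactive_i,B1,-0.85
inactive_i,B2,-1.00
inactive_i,B3,0.69
inactive_i,C1,1.48
inactive_i,C2,-0.81
inactive_i,C3,-0.20
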