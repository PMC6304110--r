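specimen_id,species,site,foraging_group,d13C,d15N
savannah_open_sp01_iso01,savannah_open_sp01,savannah,open,-21.03,11.13
savannah_open_sp01_iso02,savannah_open_sp01,savannah,open,-20.83,10.64
savannah_open_sp01_iso03,savannah_open_sp01,savannah,open,-20.45,10.27
savannah_open_sp02_iso01,savannah_open_sp02,savannah,open,-19.25,11.4
savannah_open_sp02_iso02,savannah_open_sp02,savannah,open,-19.49,10.84
savannah_open_sp02_iso03,savannah_open_sp02,savannah,open,-19.29,11.21
savannah_edge_sp01_iso01,savannah_edge_sp01,savannah,edge,-19.98,8.66
savannah_edge_sp01_iso02,savannah_edge_sp01,savannah,edge,-20.4,8.75
savannah_edge_sp01_iso03,savannah_edge_sp01,savannah,edge,-20.53,8.05
savannah_edge_sp02_iso01,savannah_edge_sp02,savannah,edge,-18.37,10.81
savannah_edge_sp02_iso02,savannah_edge_sp02,savannah,edge,-17.95,12.46
savannah_edge_sp02_iso03,savannah_edge_sp02,savannah,edge,-17.61,11.39
savannah_edge_sp03_iso01,savannah_edge_sp03,savannah,edge,-18.69,11.43
savannah_edge_sp03_iso02,savannah_edge_sp03,savannah,edge,-18.25,12.04
savannah_edge_sp03_iso03,savannah_edge_sp03,savannah,edge,-18.27,12.07
savannah_edge_sp04_iso01,savannah_edge_sp04,savannah,edge,-18.94,9.09
savannah_edge_sp04_iso02,savannah_edge_sp04,savannah,edge,-18.1,8.79
savannah_edge_sp04_iso03,savannah_edge_sp04,savannah,edge,-18.15,9.79
savannah_edge_sp05_iso01,savannah_edge_sp05,savannah,edge,-20.11,11.4
savannah_edge_sp05_iso02,savannah_edge_sp05,savannah,edge,-19.09,12.33
savannah_edge_sp05_iso03,savannah_edge_sp05,savannah,edge,-19.29,11.73
savannah_edge_sp06_iso01,savannah_edge_sp06,savannah,edge,-18.56,9.93
savannah_edge_sp06_iso02,savannah_edge_sp06,savannah,edge,-19.62,10.19
savannah_edge_sp06_iso03,savannah_edge_sp06,savannah,edge,-18.68,9.93
savannah_edge_sp07_iso01,savannah_edge_sp07,savannah,edge,-18.13,9.35
savannah_edge_sp07_iso02,savannah_edge_sp07,savannah,edge,-18.87,8.9
savannah_edge_sp07_iso03,savannah_edge_sp07,savannah,edge,-18.35,8.42
savannah_edge_sp08_iso01,savannah_edge_sp08,savannah,edge,-18.59,12.19
savannah_edge_sp08_iso02,savannah_edge_sp08,savannah,edge,-18.07,11.23
savannah_edge_sp08_iso03,savannah_edge_sp08,savannah,edge,-17.88,12.22
savannah_clutter_sp01_iso01,savannah_clutter_sp01,savannah,clutter,-21.85,9.49
savannah_clutter_sp01_iso02,savannah_clutter_sp01,savannah,clutter,-22.26,9.87
savannah_clutter_sp01_iso03,savannah_clutter_sp01,savannah,clutter,-21.08,9.82
savannah_clutter_sp02_iso01,savannah_clutter_sp02,savannah,clutter,-18.34,12.88
savannah_clutter_sp02_iso02,savannah_clutter_sp02,savannah,clutter,-19.8,11.77
savannah_clutter_sp02_iso03,savannah_clutter_sp02,savannah,clutter,-20.06,12.05
savannah_clutter_sp03_iso01,savannah_clutter_sp03,savannah,clutter,-20.62,10.59
savannah_clutter_sp03_iso02,savannah_clutter_sp03,savannah,clutter,-19.69,11.43
savannah_clutter_sp03_iso03,savannah_clutter_sp03,savannah,clutter,-20.05,11.29
savannah_clutter_sp04_iso01,savannah_clutter_sp04,savannah,clutter,-21.04,12.51
savannah_clutter_sp04_iso02,savannah_clutter_sp04,savannah,clutter,-21.54,11.85
savannah_clutter_sp04_iso03,savannah_clutter_sp04,savannah,clutter,-20.73,11.28
savannah_clutter_sp05_iso01,savannah_clutter_sp05,savannah,clutter,-22.9,7.66
savannah_clutter_sp05_iso02,savannah_clutter_sp05,savannah,clutter,-21.89,7.86
savannah_clutter_sp05_iso03,savannah_clutter_sp05,savannah,clutter,-23.47,7.67
savannah_clutter_sp06_iso01,savannah_clutter_sp06,savannah,clutter,-20.32,7.71
savannah_clutter_sp06_iso02,savannah_clutter_sp06,savannah,clutter,-19.61,8.34
savannah_clutter_sp06_iso03,savannah_clutter_sp06,savannah,clutter,-19.24,7.77
savannah_fruitbat_sp01_iso01,savannah_fruitbat_sp01,savannah,fruitbat,-23.23,8.18
savannah_fruitbat_sp01_iso02,savannah_fruitbat_sp01,savannah,fruitbat,-24.25,7.39
savannah_fruitbat_sp01_iso03,savannah_fruitbat_sp01,savannah,fruitbat,-24.08,7.95
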