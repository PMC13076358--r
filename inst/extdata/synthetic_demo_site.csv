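id,site,x,y,dbh,hap,loc01_a,loc01_b,loc02_a,loc02_b,loc03_a,loc03_b,loc04_a,loc04_b
tree01,demo,176.2,183.4,43.2,H3,1,1,3,5,1,3,1,5
tree02,demo,114.6,91,48.3,H1,4,5,1,5,3,3,1,1
tree03,demo,177.5,117.8,95.3,H1,1,5,2,2,1,3,1,2
tree04,demo,172,58.4,191.5,H3,1,4,1,3,1,3,1,1
tree05,demo,151.2,193.4,36.4,H1,1,5,1,5,3,5,1,2
tree06,demo,125.1,134.4,43.8,H3,1,5,3,5,1,3,1,1
tree07,demo,112.7,155.1,37.7,H1,1,5,1,3,1,1,1,3
tree08,demo,161.9,138.6,67,H1,1,5,3,3,3,3,3,3
tree09,demo,158.9,104.8,57.9,H1,5,5,2,5,1,3,1,3
tree10,demo,112.5,132.2,39.1,H1,2,5,2,3,1,3,2,2
tree11,demo,150.3,175.5,39.3,H4,1,2,2,2,3,3,2,2
tree12,demo,156,141.9,29.9,H1,1,5,2,3,1,3,3,3
tree13,demo,163.2,125.4,13.5,H1,5,5,1,5,3,3,1,3
tree14,demo,151.5,103.4,5.5,H1,4,5,5,5,3,3,1,3
tree15,demo,129.2,63.7,5.4,H1,5,5,2,3,1,3,1,3
tree16,demo,131.1,98.4,14.9,H1,2,5,2,3,1,3,1,2
tree17,demo,166.2,149,6.7,H1,1,5,3,5,3,3,1,3
tree18,demo,140.1,137.4,4.1,H3,1,5,1,5,1,3,1,2
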