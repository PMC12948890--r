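table,group,subgroup,n,t2_rest,t2_21k,t2_control,delta_run_ms,delta_run_pct,delta_ctrl_ms,delta_ctrl_pct,pri_printed
global,Total,,57,43.1,42.2,43.1,-0.9,-2.0,0.1,0.2,1.0
global,Laterality,Left,30,42.8,41.9,42.5,-0.9,-2.0,-0.3,-0.6,0.8
global,Laterality,Right,27,43.4,42.5,43.8,-0.9,-2.1,0.4,1.0,1.2
global,Sex,Male,42,43.6,42.7,43.7,-0.9,-2.0,0.0,0.1,1.1
global,Sex,Female,15,41.5,40.6,41.6,-0.9,-2.1,0.1,0.4,1.1
compartment,LF,,57,45.0,44.4,45.0,-0.5,-1.1,0.0,0.1,1.0
compartment,LT,,57,36.4,36.9,36.0,0.6,2.0,-0.4,-0.7,1.8
compartment,MF,,57,45.9,44.2,45.3,-1.7,-3.4,-0.6,-1.2,0.6
compartment,MT,,57,40.8,38.5,41.4,-2.3,-5.2,0.6,2.1,1.3
compartment,LatC,,57,42.4,40.7,40.5,-1.8,-4.1,-2.0,-4.7,-0.1
compartment,MedC,,57,43.7,41.4,43.4,-2.3,-5.3,-0.3,-0.7,0.9
compartment,LPF,,57,44.2,43.8,44.4,-0.3,-0.4,0.4,1.2,1.5
compartment,TrPF,,57,44.0,42.8,44.2,-1.2,-2.7,0.2,0.6,1.2
section,LF,Anterior,57,45.8,45.7,45.9,-0.1,0.2,0.1,0.7,2.0
section,LF,Central,57,42.7,42.0,42.4,-0.8,-1.9,-0.5,-1.0,0.6
section,LF,Posterior,57,46.3,45.6,46.6,-0.7,-1.3,0.3,0.8,1.4
section,LT,Anterior,57,35.4,35.9,36.1,0.6,2.2,0.7,2.7,-0.4
section,LT,Central,57,31.0,32.5,30.5,1.5,5.4,-0.5,-1.3,1.3
section,LT,Posterior,57,42.7,42.4,41.4,-0.4,0.3,-1.4,-2.8,-3.3
section,MF,Anterior,57,47.0,45.3,46.3,-1.8,-2.6,-0.8,-1.0,0.6
section,MF,Central,57,40.7,39.7,40.1,-1.0,-2.3,-0.6,-1.4,0.4
section,MF,Posterior,57,49.9,47.6,49.5,-2.3,-4.5,-0.4,-0.8,0.8
section,MT,Anterior,57,44.0,41.3,45.5,-2.6,-5.0,1.5,4.1,1.6
section,MT,Central,57,37.5,35.1,38.0,-2.4,-5.3,0.5,2.3,1.2
section,MT,Posterior,57,41.0,39.1,40.9,-2.0,-4.6,-0.2,-0.2,0.9
section,LPF,LPpf,57,41.4,41.1,41.8,-0.3,-0.4,0.4,1.2,2.3
section,LPF,LFpf,57,47.0,46.4,47.0,-0.5,-1.0,-0.0,-0.0,1.0
section,TrPF,Pt,57,43.4,42.2,43.7,-1.2,-2.5,0.2,0.7,1.3
section,TrPF,Ft,57,44.6,43.3,44.8,-1.3,-2.7,0.2,0.6,1.2
subgroup,LF,Left,30,44.6,44.1,44.4,-0.5,-0.9,-0.2,-0.4,0.6
subgroup,LF,Right,27,45.4,44.8,45.6,-0.6,-1.2,0.2,0.5,1.3
subgroup,LF,Male,42,46.0,45.2,45.7,-0.8,-1.6,-0.3,-0.5,0.6
subgroup,LF,Female,15,42.2,42.4,42.8,0.2,0.5,0.7,1.7,-2.0
subgroup,LT,Left,30,36.3,38.2,36.4,1.9,5.7,0.1,0.9,0.9
subgroup,LT,Right,27,36.5,35.6,35.5,-0.9,-2.2,-0.9,-2.6,-0.1
subgroup,LT,Male,42,35.9,36.6,36.0,0.7,2.3,0.0,0.3,0.9
subgroup,LT,Female,15,37.6,37.8,36.0,0.2,1.1,-1.6,-3.6,9.0
subgroup,MF,Left,30,46.3,44.3,45.5,-1.9,-3.9,-0.7,-1.4,0.6
subgroup,MF,Right,27,45.5,44.1,45.0,-1.4,-2.8,-0.5,-0.9,0.6
subgroup,MF,Male,42,46.7,44.7,46.0,-2.0,-4.0,-0.7,-1.3,0.6
subgroup,MF,Female,15,43.7,42.9,43.3,-0.8,-1.7,-0.4,-1.0,0.5
subgroup,MT,Left,30,40.7,37.8,39.7,-2.9,-6.5,-1.1,-1.8,0.7
subgroup,MT,Right,27,40.9,39.3,43.4,-1.7,-3.8,2.5,6.3,2.6
subgroup,MT,Male,42,42.1,39.7,43.1,-2.4,-5.1,1.0,3.2,1.4
subgroup,MT,Female,15,37.3,35.1,36.7,-2.2,-5.9,-0.6,-1.3,0.7
subgroup,LatC,Left,30,41.7,41.2,40.4,-0.5,-1.3,-1.3,-3.1,-1.6
subgroup,LatC,Right,27,43.3,40.2,40.5,-3.1,-7.2,-2.8,-6.4,0.1
subgroup,LatC,Male,42,42.7,40.9,40.8,-1.8,-4.2,-1.9,-4.4,-0.1
subgroup,LatC,Female,15,41.7,40.1,39.5,-1.6,-3.9,-2.3,-5.5,-0.4
subgroup,MedC,Left,30,43.9,41.1,42.6,-2.8,-6.4,-1.3,-2.9,0.5
subgroup,MedC,Right,27,43.4,41.7,44.2,-1.7,-4.1,0.8,1.7,1.5
subgroup,MedC,Male,42,44.5,42.2,44.6,-2.3,-5.3,0.0,0.1,1.0
subgroup,MedC,Female,15,41.3,39.0,40.0,-2.3,-5.5,-1.3,-3.0,0.4
subgroup,LPF,Left,30,42.1,41.9,42.5,-0.3,-0.3,0.4,1.3,3.0
subgroup,LPF,Right,27,40.6,40.3,41.1,-0.4,-0.6,0.5,1.1,2.7
subgroup,LPF,Male,42,41.1,41.4,41.2,0.3,1.0,0.1,0.5,0.7
subgroup,LPF,Female,15,42.4,40.3,43.7,-2.0,-4.4,1.3,3.4,1.6
subgroup,TrPF,Left,30,44.3,43.0,44.4,-1.3,-2.8,0.1,0.3,1.1
subgroup,TrPF,Right,27,43.6,42.5,44.0,-1.1,-2.5,0.4,0.9,1.4
subgroup,TrPF,Male,42,44.7,43.6,44.6,-1.1,-2.3,-0.1,-0.1,0.9
subgroup,TrPF,Female,15,42.0,40.4,43.1,-1.6,-3.7,1.1,2.6,1.7
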