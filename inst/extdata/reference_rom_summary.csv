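side,joint,plane,mean,sd,max,min,rom
left,hip,flexion_extension,101.7,15.7,129.6,82.2,47.4
left,hip,internal_external,4.9,3.9,10.9,-3.7,14.6
left,hip,abduction_adduction,-7.0,4.6,0.5,-14.4,14.9
left,stifle,flexion_extension,128.1,10.9,143.7,106.5,37.2
left,stifle,internal_external,-8.6,2.8,-3.2,-14.5,11.3
left,stifle,abduction_adduction,-7.4,3.5,-0.9,-16.2,15.3
left,tarsus,flexion_extension,117.0,6.0,129.8,105.8,24.0
left,tarsus,internal_external,9.3,8.2,24.7,-0.1,24.9
left,tarsus,abduction_adduction,5.3,2.3,9.4,0.7,8.7
right,hip,flexion_extension,101.7,14.8,129.5,84.5,45.1
right,hip,internal_external,12.3,3.4,17.7,4.8,12.9
right,hip,abduction_adduction,5.7,3.7,14.1,1.4,12.7
right,stifle,flexion_extension,126.9,11.0,141.2,103.7,37.5
right,stifle,internal_external,-5.0,3.5,-1.1,-13.5,12.4
right,stifle,abduction_adduction,-3.5,2.5,-0.9,-8.9,8.0
right,tarsus,flexion_extension,117.2,7.1,133.4,103.8,29.6
right,tarsus,internal_external,19.0,7.2,29.9,19.3,10.7
right,tarsus,abduction_adduction,8.2,1.2,10.9,5.9,5.0
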