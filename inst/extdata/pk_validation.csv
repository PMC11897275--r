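regimen_label,parameter,day,predicted,observed,printed_error_pct
600 mg IV SD,Cmax,NA,31.9,37.6,-15.16
600 mg IV SD,Tmax,NA,1,1.06,-5.66
600 mg IV SD,AUC,NA,93.73,114,-17.78
600 mg IV SD,V,NA,18.28,13.67,33.72
600 mg IV SD,CL,NA,6.24,5.15,21.17
600 mg IV SD,T1/2,NA,2.22,2.21,0.45
200 mg oral SD,Cmax,NA,8.92,10.3,15.59
200 mg oral SD,Tmax,NA,1.98,1.7,-14.57
200 mg oral SD,AUC,NA,49.6,60,20.94
200 mg oral SD,V/F,NA,44.24,50.88,-13.05
200 mg oral SD,CL/F,NA,7.9,10.49,-24.69
200 mg oral SD,T1/2,NA,3.63,2.74,32.32
400 mg oral SD,Cmax,NA,11.53,8.71,-24.5
400 mg oral SD,Tmax,NA,1.92,1.85,-3.77
400 mg oral SD,AUC,NA,59.41,41.56,-30.05
400 mg oral SD,V/F,NA,46.03,42.12,9.29
400 mg oral SD,CL/F,NA,8.94,7.81,14.54
400 mg oral SD,T1/2,NA,3.37,2.95,14.24
600 mg oral QD-1,Cmax,1,14.2,13,9.23
600 mg oral QD-1,AUC,1,70.34,85.63,-17.86
600 mg oral QD-1,V/F,1,35.27,61.44,-42.59
600 mg oral QD-1,CL/F,1,8.52,6.23,36.76
600 mg oral QD-1,T1/2,1,2.54,11.54,-77.99
600 mg oral QD-1,Cmax,4,11.3,11.3,0
600 mg oral QD-1,AUC,4,43.74,48.43,-9.68
600 mg oral QD-1,V/F,4,44.76,50.74,-11.79
600 mg oral QD-1,CL/F,4,12.74,9.86,29.21
600 mg oral QD-1,T1/2,4,2.06,3.43,-39.94
600 mg oral QD-1,Cmax,6,11.2,10.2,9.8
600 mg oral QD-1,AUC,6,41.24,34.05,21.12
600 mg oral QD-1,V/F,6,44.24,54.92,-19.45
600 mg oral QD-1,CL/F,6,12.96,15.98,-18.9
600 mg oral QD-1,T1/2,6,1.92,1.4,37.14
600 mg oral QD-2,Cmax,1,20.3,22,-7.73
600 mg oral QD-2,AUC,1,89.34,132.27,-32.46
600 mg oral QD-2,V/F,1,23.9,21.98,56.53
600 mg oral QD-2,CL/F,1,6.59,4.21,-22.9
600 mg oral QD-2,T1/2,1,2.02,2.62,-4.11
600 mg oral QD-2,Cmax,4,15.9,13,22.31
600 mg oral QD-2,AUC,4,57.55,86.76,-33.67
600 mg oral QD-2,V/F,4,32.47,33.86,56.4
600 mg oral QD-2,CL/F,4,10.26,6.56,5.24
600 mg oral QD-2,T1/2,4,2.21,2.1,56.53
600 mg oral QD-2,Cmax,7,15.8,17.7,-10.73
600 mg oral QD-2,AUC,7,57,96.73,-41.07
600 mg oral QD-2,V/F,7,32.48,25.26,28.58
600 mg oral QD-2,CL/F,7,10.36,6.11,69.56
600 mg oral QD-2,T1/2,7,2.2,1.46,50.68
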