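electrode,depth,delta_v_mV
Fp1,Z0,15800.0
Fp1,Z33,41200.0
Fp1,Z66,48400.0
Fp1,Z100,53200.0
Fpz,Z0,8080.0
Fpz,Z33,15600.0
Fpz,Z66,41600.0
Fpz,Z100,16600.0
Fp2,Z0,39600.0
Fp2,Z33,42800.0
Fp2,Z66,50400.0
Fp2,Z100,42400.0
F7,Z0,39200.0
F7,Z33,40800.0
F7,Z66,44000.0
F7,Z100,42400.0
F3,Z0,35600.0
F3,Z33,39600.0
F3,Z66,40400.0
F3,Z100,54000.0
Fz,Z0,32000.0
Fz,Z33,34400.0
Fz,Z66,44000.0
Fz,Z100,49600.0
F4,Z0,29200.0
F4,Z33,33600.0
F4,Z66,44400.0
F4,Z100,51600.0
F8,Z0,31600.0
F8,Z33,35600.0
F8,Z66,42800.0
F8,Z100,47600.0
T3,Z0,30800.0
T3,Z33,32000.0
T3,Z66,35200.0
T3,Z100,36800.0
C3,Z0,NR
C3,Z33,NR
C3,Z66,NR
C3,Z100,NR
Cz,Z0,28000.0
Cz,Z33,33200.0
Cz,Z66,43600.0
Cz,Z100,52000.0
C4,Z0,NR
C4,Z33,NR
C4,Z66,NR
C4,Z100,NR
T4,Z0,29200.0
T4,Z33,32000.0
T4,Z66,36800.0
T4,Z100,38000.0
T5,Z0,29600.0
T5,Z33,32800.0
T5,Z66,34800.0
T5,Z100,37600.0
P3,Z0,28000.0
P3,Z33,30000.0
P3,Z66,36000.0
P3,Z100,43200.0
Pz,Z0,24400.0
Pz,Z33,27600.0
Pz,Z66,34400.0
Pz,Z100,36700.0
P4,Z0,24000.0
P4,Z33,27200.0
P4,Z66,32400.0
P4,Z100,36800.0
T6,Z0,21600.0
T6,Z33,24800.0
T6,Z66,28000.0
T6,Z100,31600.0
O1,Z0,26400.0
O1,Z33,28800.0
O1,Z66,33200.0
O1,Z100,33200.0
Oz,Z0,22800.0
Oz,Z33,25200.0
Oz,Z66,29200.0
Oz,Z100,33200.0
O2,Z0,22000.0
O2,Z33,24400.0
O2,Z66,28800.0
O2,Z100,34800.0
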