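# Benchmark (dimensionless) parameter regime, keyed by model name.
# Row labels mirror the published benchmark parameter table; "X" cells of
# the table are omitted keys.  "Pulse amplitude" is a package-level default
# for demonstration traces, not a table row.
LIF:
  Time step: 0.1
  Tau: 4.0
  Reset potential: 0.0
  Threshold value: 1.0
  Initial potential: 0.1
  Pulse amplitude: 2.0
NLIF:
  Time step: 0.1
  Tau: 4.0
  Reset potential: 0.0
  Threshold value: 1.0
  Initial potential: 0.5
  Alpha: 0.5
  Beta: 0.5
  Pulse amplitude: 25.0
AdEx:
  Time step: 0.1
  Tau: 4.0
  Reset potential: 0.1
  Initial potential: 0.1
  Rheobase potential: 0.5
  Threshold potential: 1.0
  Slope factor: 1.0
  Pulse amplitude: 1.0
HH:
  Time step: 0.1
  Tau: 4.0
  Reset potential: -65.0
  Initial potential: -65.0
  Activation variable for potassium: 0.3177
  Activation variable for sodium: 0.0529
  Inactivation variable for sodium: 0.5961
  Maximum conductance gNa: 120.0
  Maximum conductance gK: 36.0
  Maximum conductance gL: 0.3
  Sodium reversal potential: 50.0
  Potassium reversal potential: -77.0
  Leak reversal potential: -54.4
  Pulse amplitude: 10.0
IFSFA:
  Time step: 0.1
  Tau: 4.0
  Reset potential: 0.0
  Threshold value: 1.0
  Initial potential: -0.1
  Slope factor: 2.0
  Adaptation time constant: 100.0
  Adaptation conductance: 0.1
  Adaptation control: 0.01
  Pulse amplitude: 2.0
QIF:
  Time step: 0.1
  Tau: 4.0
  Reset potential: 0.0
  Threshold value: 1.0
  Initial potential: -0.1
  Beta: 0.5
  Pulse amplitude: 2.0
ThetaNeuron:
  Time step: 0.1
  Tau: 4.0
  Reset potential: 0.0
  Threshold value: 1.0
  Initial potential: 0.0
  Pulse amplitude: 2.0
SRM:
  Time step: 0.1
  Tau: 0.3
  Reset potential: 0.0
  Threshold value: 1.0
  Initial potential: 0.0
  Synaptic time constants: 10.0
  Pulse amplitude: -3.0
Izhikevich:
  Time step: 0.1
  Threshold value: 0.8
  Initial potential: 0.01
  Recovery variable initial: 0.2
  Time scale RV: 0.02
  Sensitivity RV: 0.2
  After-spike reset MP: 0.1
  After-spike reset RV: 0.06
  Pulse amplitude: 1.0
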