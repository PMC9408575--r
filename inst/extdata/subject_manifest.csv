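subject_id,sex,age,n_sessions
A,Male,22,4
B,Female,22,4
C,Male,23,4
D,Female,22,4
E,Male,22,4
F,Female,21,8
G,Male,22,8
H,Female,22,8
I,Male,24,8
J,Female,22,8
K,Male,22,4
L,Female,22,4
M,Male,21,4
N,Female,22,4
O,Male,22,4
P,Female,22,8
Q,Male,20,8
R,Female,22,8
S,Male,23,8
T,Female,22,8
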