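group,code,confidence_pct
self-winding,A,99
self-winding,J,99
self-winding,O,99
self-winding,V,99
adhesion,B,99
adhesion,D,99
adhesion,F,99
adhesion,H,66
adhesion,K,96
adhesion,M,99
adhesion,P,90
adhesion,T,99
adhesion,W,99
inter-overlapped,C,99
inter-overlapped,E,99
inter-overlapped,G,41
inter-overlapped,I,80
inter-overlapped,L,99
inter-overlapped,N,67
inter-overlapped,Q,99
inter-overlapped,S,99
inter-overlapped,X,99
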