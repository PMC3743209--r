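id,name,family,stereo,R1,R2,R3,R4,R5,R6,pEC50_DAT,pEC50_SERT
1,Dopamine,phenylethylamine,achiral,H,H,H,H,OH,OH,7.1,5.0
2,Tyramine,phenylethylamine,achiral,H,H,H,H,H,OH,6.9,5.6
3,Norepinephrine,phenylethylamine,S,H,H,H,OH,OH,OH,6.1,5.0
4,(S)-Amphetamine,phenylethylamine,S,H,Me,H,H,H,H,7.6,5.6
5,(R)-Ephedrine,phenylethylamine,R,Me,Me,H,OH,OH,OH,5.9,5.0
6,HMA,phenylethylamine,racemic,H,Me,H,H,H,OH,5.5,6.1
7,(R)-Methamphetamine,phenylethylamine,R,Me,Me,H,H,H,H,6.4,5.3
8,(S)-Methamphetamine,phenylethylamine,S,Me,Me,H,H,H,H,7.6,6.1
9,m-Methylamphetamine,phenylethylamine,racemic,H,Me,H,H,Me,H,7.5,6.7
10,p-Methylamphetamine,phenylethylamine,racemic,H,Me,H,H,H,Me,7.5,6.7
11,Phentermine,phenylethylamine,achiral,H,Me,Me,H,H,H,6.6,5.5
12,Chlorphentermine,phenylethylamine,achiral,H,Me,Me,H,H,Cl,5.6,7.5
13,m-Fluoroamphetamine,phenylethylamine,racemic,H,Me,H,H,F,H,7.6,5.7
14,p-Fluoroamphetamine,phenylethylamine,racemic,H,Me,H,H,H,F,7.3,6.0
15,HMMA,phenylethylamine,racemic,Me,Me,H,H,MeO,OH,5.5,6.2
16,(R)-Norfenfluramine,phenylethylamine,R,H,Me,H,H,CF3,H,5.0,6.5
17,(S)-Norfenfluramine,phenylethylamine,S,H,Me,H,H,CF3,H,6.0,7.2
18,(R)-Fenfluramine,phenylethylamine,R,Et,Me,H,H,CF3,H,5.0,6.8
19,(S)-Fenfluramine,phenylethylamine,S,Et,Me,H,H,CF3,H,5.0,7.3
20,MDA,methylenedioxyamphetamine,racemic,H,H,H,H,H,H,7.0,7.0
21,(S)-MDMA,methylenedioxyamphetamine,S,Me,H,H,H,H,H,7.3,7.3
22,(S)-MDEA,methylenedioxyamphetamine,S,Et,H,H,H,H,H,6.3,7.3
23,NIPA,naphtylisopropylamine,racemic,H,H,H,H,H,H,7.8,8.4
24,(S)-N-Methyl-NIPA,naphtylisopropylamine,S,Me,H,H,H,H,H,8.0,7.9
25,(S)-N-Ethyl-NIPA,naphtylisopropylamine,S,Et,H,H,H,H,H,7.3,7.9
26,Methcathinone,cathinone,racemic,Me,H,H,H,H,H,7.7,5.4
27,Mephedrone,cathinone,racemic,Me,H,H,H,H,Me,7.3,6.9
28,PAL-738,other,achiral,H,H,H,H,H,H,7.2,7.6
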