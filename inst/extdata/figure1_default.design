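# Default bifurcating-deme serial-passage design: 16 tips, 15 internal nodes
# and 1 ancestor (32 sequenced clones).  Level durations are 50, 50, 50, 100,
# 100 generations (10/10/10/20/20 days at 5 generations per day), giving 350
# generations root-to-tip and 2750 generations summed over all branches.
# schedule: comma-separated bottleneck sizes, each held for an equal share of
# the branch days ("1000" = constant N, "1" = daily single-plaque transfer).
# host: PP, ERA, or ALT (daily alternation starting on PP).
branch	parent	host	schedule	days	gens_per_day
B1	A1	PP	1000	10	5
C1	B1	ERA	1000	10	5
C2	B1	PP	1000	10	5
D1	C1	ERA	1000	10	5
D2	C1	ERA	1000	10	5
D3	C2	PP	1000	10	5
D4	C2	PP	1000	10	5
E1	D1	PP	1	20	5
E2	D1	ERA	1	20	5
E3	D2	ALT	1	20	5
E4	D2	ERA	1000	20	5
E5	D3	PP	1	20	5
E6	D3	ERA	1	20	5
E7	D4	ALT	1	20	5
E8	D4	PP	1000	20	5
F1	E1	PP	10,100,1000,10000	20	5
F2	E1	PP	10000,1000,100,10	20	5
F3	E2	PP	10,100,1000,10000	20	5
F4	E2	PP	10000,1000,100,10	20	5
F5	E3	PP	10,100,1000,10000	20	5
F6	E3	PP	10000,1000,100,10	20	5
F7	E4	PP	1000	20	5
F8	E4	ERA	1000	20	5
F9	E5	PP	10,100,1000,10000	20	5
F10	E5	PP	10000,1000,100,10	20	5
F11	E6	PP	10,100,1000,10000	20	5
F12	E6	PP	10000,1000,100,10	20	5
F13	E7	PP	10,100,1000,10000	20	5
F14	E7	PP	10000,1000,100,10	20	5
F15	E8	ERA	1000	20	5
F16	E8	PP	1000	20	5
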