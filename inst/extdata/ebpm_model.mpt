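# mpt model declaration v1
param P free
param M free
param C1 free
param C2 free
param g fixed 0.10000000000000001
param c fixed 0.5
param M1 equated M
param M2 equated M
branch target_match C1+,P+,M1+ pm
branch target_match C1+,P+,M1-,g+ pm
branch target_match C1+,P+,M1-,g- match
branch target_match C1+,P- match
branch target_match C1-,P+,M1+ pm
branch target_match C1-,P+,M1-,g+ pm
branch target_match C1-,P+,M1-,g-,c+ match
branch target_match C1-,P+,M1-,g-,c- nonmatch
branch target_match C1-,P-,c+ match
branch target_match C1-,P-,c- nonmatch
branch target_nonmatch C2+,P+,M1+ pm
branch target_nonmatch C2+,P+,M1-,g+ pm
branch target_nonmatch C2+,P+,M1-,g- nonmatch
branch target_nonmatch C2+,P- nonmatch
branch target_nonmatch C2-,P+,M1+ pm
branch target_nonmatch C2-,P+,M1-,g+ pm
branch target_nonmatch C2-,P+,M1-,g-,c+ match
branch target_nonmatch C2-,P+,M1-,g-,c- nonmatch
branch target_nonmatch C2-,P-,c+ match
branch target_nonmatch C2-,P-,c- nonmatch
branch distractor_match C1+,P+,M2+ match
branch distractor_match C1+,P+,M2-,g+ pm
branch distractor_match C1+,P+,M2-,g- match
branch distractor_match C1+,P- match
branch distractor_match C1-,P+,M2+,c+ match
branch distractor_match C1-,P+,M2+,c- nonmatch
branch distractor_match C1-,P+,M2-,g+ pm
branch distractor_match C1-,P+,M2-,g-,c+ match
branch distractor_match C1-,P+,M2-,g-,c- nonmatch
branch distractor_match C1-,P-,c+ match
branch distractor_match C1-,P-,c- nonmatch
branch distractor_nonmatch C2+,P+,M2+ nonmatch
branch distractor_nonmatch C2+,P+,M2-,g+ pm
branch distractor_nonmatch C2+,P+,M2-,g- nonmatch
branch distractor_nonmatch C2+,P- nonmatch
branch distractor_nonmatch C2-,P+,M2+,c+ match
branch distractor_nonmatch C2-,P+,M2+,c- nonmatch
branch distractor_nonmatch C2-,P+,M2-,g+ pm
branch distractor_nonmatch C2-,P+,M2-,g-,c+ match
branch distractor_nonmatch C2-,P+,M2-,g-,c- nonmatch
branch distractor_nonmatch C2-,P-,c+ match
branch distractor_nonmatch C2-,P-,c- nonmatch
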