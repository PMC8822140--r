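category,part,code,description
cerebral_palsy,probable,XE2Q8,
cerebral_palsy,probable,XE15M,
cerebral_palsy,probable,X00En,
cerebral_palsy,probable,Xab3R,
cerebral_palsy,probable,XaYgp,
cerebral_palsy,probable,XaYfK,
cerebral_palsy,probable,X00Eo,
cerebral_palsy,probable,XE2se,
cerebral_palsy,probable,XM1Pw,
cerebral_palsy,probable,XE2Q9,
cerebral_palsy,probable,F2300,
cerebral_palsy,probable,F230z,
cerebral_palsy,probable,X00Ep,
cerebral_palsy,probable,XM1Px,
cerebral_palsy,probable,F230.,
cerebral_palsy,probable,X00Eq,
cerebral_palsy,probable,F231.,
cerebral_palsy,probable,F234.,
cerebral_palsy,probable,XE15V,
cerebral_palsy,probable,X00Er,
cerebral_palsy,probable,X00Es,
cerebral_palsy,probable,XM1Pv,
cerebral_palsy,probable,X00Eu,
cerebral_palsy,probable,XaadE,
cerebral_palsy,probable,XE2Q7,
cerebral_palsy,probable,X00Ew,
cerebral_palsy,probable,Xa0lM,
cerebral_palsy,probable,F23y0,
cerebral_palsy,probable,Xa0lI,
cerebral_palsy,probable,X00Ex,
cerebral_palsy,probable,F23y1,
cerebral_palsy,probable,X00Ey,
cerebral_palsy,probable,X00Ez,
cerebral_palsy,probable,XaNWb,
cerebral_palsy,probable,X00F1,
cerebral_palsy,probable,X00F2,
cerebral_palsy,probable,X00F3,
cerebral_palsy,probable,F23y.,
cerebral_palsy,probable,F23yz,
cerebral_palsy,probable,F23z.,
cerebral_palsy,probable,X00Em,
cerebral_palsy,probable,Fyu90,
cerebral_palsy,probable,XM1Pu,
cerebral_palsy,probable,XaBE2,
cerebral_palsy,probable,F1371,
cerebral_palsy,probable,F23..,
cerebral_palsy,probable,XE181,
cerebral_palsy,probable,F23y0,
cerebral_palsy,probable,Xa0lM,
cerebral_palsy,probable,F2B2.,
cerebral_palsy,probable,Xab3R,
cerebral_palsy,probable,.F32Z,
cerebral_palsy,probable,F23y.,
cerebral_palsy,probable,F23yz,
cerebral_palsy,probable,F23z.,
cerebral_palsy,probable,F2B..,
cerebral_palsy,probable,F2By.,
cerebral_palsy,probable,F2Bz.,
cerebral_palsy,probable,Fyu90,
cerebral_palsy,probable,X00Em,
cerebral_palsy,probable,F23y6,
cerebral_palsy,probable,XaadE,
cerebral_palsy,probable,XM1Pu,
cerebral_palsy,probable,F23y3,
cerebral_palsy,probable,X00Eu,
cerebral_palsy,probable,F2301,
cerebral_palsy,probable,F23y2,
cerebral_palsy,probable,X00En,
cerebral_palsy,probable,XE2Q9,
cerebral_palsy,probable,XM1Pv,
cerebral_palsy,probable,XaaVG,
cerebral_palsy,probable,XaaWF,
cerebral_palsy,probable,XaaVJ,
cerebral_palsy,probable,XaaWE,
cerebral_palsy,probable,XaaVK,
cerebral_palsy,probable,XaaWD,
cerebral_palsy,probable,XaaVI,
down_syndrome,probable,.N721,
down_syndrome,probable,XE1MZ,
down_syndrome,probable,PJ00.,
down_syndrome,probable,PJ01.,
down_syndrome,probable,PJ02.,
down_syndrome,probable,X78El,
down_syndrome,probable,PJ0z.,
down_syndrome,probable,X78Ek,
down_syndrome,probable,XE1MZ,
fragile_x,probable,X78FB,
fragile_x,probable,PJyy2,
fragile_x,probable,X78FC,
fragile_x,probable,X78FD,
asd,probable,X00TM,
asd,probable,XaesO,
asd,probable,XE2v2,
asd,probable,E1400,
asd,probable,E1401,
asd,probable,E140z,
asd,probable,X00TN,
asd,probable,X005S,
asd,probable,E141.,
asd,probable,E1410,
asd,probable,E1411,
asd,probable,E141z,
asd,probable,X00TP,
asd,probable,Ub1Ts,
asd,probable,Eu844,
asd,probable,Eu84y,
asd,probable,Eu84z,
asd,probable,XE1aA,
asd,probable,E140.,
asd,probable,Eu840,
asd,probable,Eu841,
asd,probable,Eu84.,
asd,probable,Eu84y,
asd,probable,Eu845,
asd,probable,.E2Z3,
asd,probable,Eu844,
asd,probable,XE1aA,
asd,probable,Eu84z,
asd,probable,Ub1Tr,
asd,probable,Ub1Tw,
mod_severe_ld,probable,E310.,
mod_severe_ld,probable,Eu710,
mod_severe_ld,probable,Eu711,
mod_severe_ld,probable,Eu71y,
mod_severe_ld,probable,Eu71z,
mod_severe_ld,probable,E311.,
mod_severe_ld,probable,Eu720,
mod_severe_ld,probable,Eu721,
mod_severe_ld,probable,Eu72y,
mod_severe_ld,probable,Eu72z,
mod_severe_ld,probable,E312.,
mod_severe_ld,probable,Eu730,
mod_severe_ld,probable,Eu731,
mod_severe_ld,probable,Eu73y,
mod_severe_ld,probable,Eu73z,
mod_severe_ld,probable,Xa3HI,
mod_severe_ld,probable,Eu7y1,
mod_severe_ld,probable,Eu7z1,
mod_severe_ld,probable,XaREu,
mod_severe_ld,probable,Xabk1,
mod_severe_ld,probable,Xa00k,
mod_severe_ld,probable,Eu73.,
mod_severe_ld,probable,Eu71.,
mod_severe_ld,probable,.E512,
mod_severe_ld,probable,Xa01E,
mod_severe_ld,probable,.E513,
mod_severe_ld,probable,Eu72.,
mod_severe_ld,probable,Xa00l,
dev_delay,potential,X76B7,
dev_delay,potential,XaX18,
dev_delay,potential,Ua14s,
dev_delay,potential,Xa40J,
dev_delay,potential,XaXCG,
dev_delay,potential,XaBBv,
dev_delay,potential,E2F..,
dev_delay,potential,E2Fy.,
dev_delay,potential,XaIsc,
dev_delay,potential,XaO45,
dev_delay,potential,XaO46,
dev_delay,potential,XaO47,
dev_delay,potential,Ub1US,
dev_delay,potential,XacSD,
dev_delay,potential,Ub1UM,
dev_delay,potential,Ub1UO,
dev_delay,potential,Ub1UQ,
dev_delay,potential,E2E1.,
dev_delay,potential,Xa09f,
dev_delay,potential,Ub1U6,
dev_delay,potential,Ub1U2,
dev_delay,potential,R0340,
gen_dev_disorders,potential,X00TQ,
gen_dev_disorders,potential,XE1Z4,
gen_dev_disorders,potential,XM1MS,
gen_dev_disorders,potential,X00TI,
gen_dev_disorders,potential,Eu8..,
gen_dev_disorders,potential,XE1Z3,
gen_dev_disorders,potential,XE1a4,
gen_dev_disorders,potential,XE1a3,
gen_dev_disorders,potential,Ub1UL,
gen_dev_disorders,potential,E2F3z,
gen_dev_disorders,potential,X00TK,
gen_dev_disorders,potential,XE1a6,
gen_dev_disorders,potential,XE1a7,
gen_dev_disorders,potential,XE2bB,
gen_dev_disorders,potential,XE1Z5,
gen_dev_disorders,potential,Ub1Tf,
gen_dev_disorders,potential,E2F5.,
gen_dev_disorders,potential,E2Fz.,
gen_dev_disorders,potential,Eu83.,
gen_dev_disorders,potential,Eu8z.,
gen_dev_disorders,potential,XE1aB,
gen_dev_disorders,potential,Ub1S4,
gen_dev_disorders,potential,X00F0,
gen_dev_disorders,potential,XM0zA,
gen_dev_disorders,potential,XE1gX,
gen_dev_disorders,potential,XM1AJ,
gen_dev_disorders,potential,Ub1UG,
gen_dev_disorders,potential,XacL0,
gen_dev_disorders,potential,XacKx,
gen_dev_disorders,potential,Ub1UR,
gen_dev_disorders,potential,Ub1UT,
gen_dev_disorders,potential,Ub1UU,
gen_dev_disorders,potential,Ub1UV,
gen_dev_disorders,potential,Ub1UW,
gen_dev_disorders,potential,Ub1UX,
gen_dev_disorders,potential,XE1a5,
gen_dev_disorders,potential,Ub1U0,
gen_disabilities,potential,E3...,
gen_disabilities,potential,XE2a3,
gen_disabilities,potential,Eu700,
gen_disabilities,potential,Eu701,
gen_disabilities,potential,Eu70y,
gen_disabilities,potential,Eu70z,
gen_disabilities,potential,Xa0ER,
gen_disabilities,potential,Xa3HI,
gen_disabilities,potential,E31..,
gen_disabilities,potential,E31z.,
gen_disabilities,potential,Eu7y0,
gen_disabilities,potential,Eu7y1,
gen_disabilities,potential,Eu7yy,
gen_disabilities,potential,Eu7yz,
gen_disabilities,potential,E3z..,
gen_disabilities,potential,Eu7y.,
gen_disabilities,potential,Eu7z0,
gen_disabilities,potential,Eu7z1,
gen_disabilities,potential,Eu7zy,
gen_disabilities,potential,Eu7zz,
gen_disabilities,potential,XE1a2,
gen_disabilities,potential,XabmM,
gen_disabilities,potential,XacF5,
gen_disabilities,potential,X00TL,
gen_disabilities,potential,XaaiS,
gen_disabilities,potential,XacF6,
gen_disabilities,potential,XaREt,
gen_disabilities,potential,Eu813,
gen_disabilities,potential,E2F2.,
gen_disabilities,potential,Eu81.,
gen_disabilities,potential,Eu81z,
gen_disabilities,potential,XE1a9,
gen_disabilities,potential,13ZK.,
generic_disability,potential,13VC5,
generic_disability,potential,13VC1,
generic_disability,potential,13VC2,
generic_disability,potential,13VC3,
generic_disability,potential,13VCZ,
generic_disability,potential,XaKYb,
generic_disability,potential,XaDyv,
generic_disability,potential,.6664,
generic_disability,potential,6665.,
generic_disability,potential,9EB4.,
generic_disability,potential,6972.,
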