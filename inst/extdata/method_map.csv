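prefix,category
965,poisoning
967,poisoning
969,poisoning
881,cutting_piercing
E950,poisoning
E951,poisoning
E952,poisoning
E953,hanging_strangulation_suffocation
E954,other
E955,firearm
E956,cutting_piercing
E957,jumping
E958,other
E959,other
X71,other
X72,firearm
X73,firearm
X74,firearm
X75,other
X76,other
X77,other
X78,cutting_piercing
X79,cutting_piercing
X80,jumping
X81,jumping
X82,other
X83,other
T1491,other
T36,poisoning
T37,poisoning
T38,poisoning
T39,poisoning
T40,poisoning
T41,poisoning
T42,poisoning
T43,poisoning
T44,poisoning
T45,poisoning
T46,poisoning
T47,poisoning
T48,poisoning
T49,poisoning
T50,poisoning
T51,poisoning
T52,poisoning
T53,poisoning
T54,poisoning
T55,poisoning
T56,poisoning
T57,poisoning
T58,poisoning
T59,poisoning
T60,poisoning
T61,poisoning
T62,poisoning
T63,poisoning
T64,poisoning
T65,poisoning
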