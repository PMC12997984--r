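family	note
GH2	beta-galactosidase / beta-glucuronidase activities on mucin O-glycans
GH3	beta-glucosidase / beta-N-acetylglucosaminidase
GH16	endo-acting O-glycanase activities
GH20	beta-hexosaminidase (GlcNAc/GalNAc removal)
GH27	alpha-galactosidase
GH29	alpha-L-fucosidase (1-3/1-4 linkages)
GH31	alpha-glucosidase / alpha-N-acetylgalactosaminidase
GH33	sialidase (neuraminidase), terminal Neu5Ac removal
GH35	beta-galactosidase
GH36	alpha-galactosidase / alpha-N-acetylgalactosaminidase
GH42	beta-galactosidase
GH43_24	beta-1,3-galactosidase subfamily active on mucin core structures
GH51	alpha-L-arabinofuranosidase-related activities
GH84	O-GlcNAcase / beta-N-acetylglucosaminidase
GH89	alpha-N-acetylglucosaminidase
GH95	alpha-L-fucosidase (1-2 linkages)
GH97	alpha-glucosidase / alpha-galactosidase
GH101	endo-alpha-N-acetylgalactosaminidase (O-glycan core 1)
GH109	alpha-N-acetylgalactosaminidase (blood-group A)
GH110	alpha-galactosidase (blood-group B)
GH111	keratan-sulfate-related endo-galactosidase
GH112	lacto-N-biose / galacto-N-biose phosphorylase
GH123	beta-N-acetylgalactosaminidase
GH136	lacto-N-biosidase
GH181	endo-acting O-glycanase on mucin glycans
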