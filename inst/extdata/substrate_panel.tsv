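# Tandem-thioredoxin reporter linker inserts (BamHI-GS ... VD-SalI frame).
# observed_site: gel-observed cleavage kind for the listed enzyme.
# inferred: TRUE where the flanking scaffold is a reconstruction from the
# stated GRGG/RGGRG design (full insert not printed); synthetic rows.
name	insert	enzyme	observed_site	inferred
VS_core	VLLVSEVL	hNE	insert	FALSE
IS_core	VLLISEVL	hNE	insert	TRUE
AS_core	VLLASEVL	hNE	sal_fallback	TRUE
FS_core	VLLFSEVL	hNE	sal_fallback	FALSE
RGG_V	GRGGVGGRG	hNE	insert	FALSE
RGG_A	GRGGAGGRG	hNE	sal_fallback	FALSE
RGG_L	GRGGLGGRG	hNE	sal_fallback	TRUE
RGG_F	GRGGFGGRG	hNE	sal_fallback	TRUE
RGG_VV	GRGVVGGRG	hNE	insert	TRUE
RGG_VVV	GRGVVVGRG	hNE	insert	TRUE
RGG_VA	GRGVAGGRG	hNE	insert	TRUE
RGG_VS	GRGGVSGRG	hNE	insert	TRUE
RGG_VR	GRGGVRGRG	hNE	insert	TRUE
RGG_VY	GRGGVYGRG	hNE	sal_fallback	TRUE
RGG_VD	GRGGVDGRG	hNE	sal_fallback	TRUE
RGG_IS	GRGGISGRG	hNE	insert	TRUE
RGG_AS	GRGGASGRG	hNE	sal_fallback	TRUE
RGG_FS	GRGGFSGRG	hNE	sal_fallback	TRUE
thrombin_site	LTPRGVRL	thrombin	insert	FALSE
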