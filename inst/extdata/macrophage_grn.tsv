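# Signed edge list of the minimal macrophage M1/M2 polarization network.
# Header section: one "#node" line per node, fields: name, role, phenotype tag.
# Roles: input (extracellular stimulus), receptor (membrane sensor), internal
# (transducer / transcription factor / target gene). Node order is the state
# bit order and is significant.
#node	IFNg	input	input
#node	IL10	input	input
#node	IL4	input	input
#node	LPS	input	input
#node	IFNgR	receptor	receptor
#node	IL10R	receptor	receptor
#node	IL4Ra	receptor	receptor
#node	TLR4	receptor	receptor
#node	STAT1	internal	M1
#node	SOCS3	internal	M1
#node	NF-kB	internal	M1
#node	NOS2	internal	M1
#node	STAT6	internal	M2
#node	PPARg	internal	M2
#node	SOCS1	internal	M2
#node	KLF4	internal	M2
#node	Arg1	internal	M2
#node	STAT3	internal	M2
IFNg	+	IFNgR
IL10	+	IL10R
IL4	+	IL4Ra
LPS	+	TLR4
IFNgR	+	STAT1
STAT1	+	SOCS3
STAT1	+	NOS2
TLR4	+	NF-kB
NF-kB	+	NOS2
IL4Ra	+	STAT6
STAT6	+	PPARg
STAT6	+	SOCS1
STAT6	+	KLF4
STAT6	+	Arg1
IL10R	+	STAT3
STAT3	+	IL4Ra
SOCS1	-	STAT1
SOCS3	-	STAT3
KLF4	-	NF-kB
PPARg	-	NF-kB
STAT3	-	NF-kB
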