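##gff-version 3
# Synthetic annotation for the simulated genome (Chr2 distal arm).
# Gene coordinates and ids are invented for demonstrating region reports;
# they do not correspond to any real genome.
Chr2	synthetic	gene	16850000	16854200	.	+	.	ID=SYNG2001;Name=SYNG2001
Chr2	synthetic	gene	17020000	17026500	.	-	.	ID=SYNG2002;Name=SYNG2002
Chr2	synthetic	gene	17210000	17213800	.	+	.	ID=SYNG2003;Name=SYNG2003
Chr2	synthetic	gene	17455000	17460900	.	+	.	ID=SYNG2004;Name=SYNG2004
Chr2	synthetic	gene	17702000	17705400	.	-	.	ID=SYNG2005;Name=SYNG2005
Chr2	synthetic	gene	17940000	17947200	.	+	.	ID=SYNG2006;Name=SYNG2006
Chr2	synthetic	gene	18180000	18183600	.	-	.	ID=SYNG2007;Name=SYNG2007
Chr2	synthetic	gene	18395000	18401100	.	+	.	ID=SYNG2008;Name=SYNG2008
Chr2	synthetic	gene	18490000	18496700	.	-	.	ID=SYNG2009;Name=SYNG2009
Chr2	synthetic	gene	18720000	18724900	.	+	.	ID=SYNG2010;Name=SYNG2010
Chr2	synthetic	gene	18955000	18961300	.	-	.	ID=SYNG2011;Name=SYNG2011
Chr2	synthetic	gene	19240000	19243500	.	+	.	ID=SYNG2012;Name=SYNG2012
Chr2	synthetic	gene	19610000	19617800	.	+	.	ID=SYNG2013;Name=SYNG2013
Chr2	synthetic	gene	19890000	19894600	.	-	.	ID=SYNG2014;Name=SYNG2014
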