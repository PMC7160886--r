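genome_id	chromosome_id	position	signed_family_id
rosid	rosid.chr1	1	m0001
rosid	rosid.chr1	2	m0006
rosid	rosid.chr1	3	-m0011
rosid	rosid.chr1	4	m0002
rosid	rosid.chr1	5	-m0004
rosid	rosid.chr1	6	-m0007
rosid	rosid.chr1	7	-m0010
rosid	rosid.chr1	8	m0009
rosid	rosid.chr1	9	-m0008
rosid	rosid.chr1	10	m0012
rosid	rosid.chr2	1	-m0003
rosid	rosid.chr2	2	m0005
asterid1	asterid1.chr1	1	m0001
asterid1	asterid1.chr1	2	m0006
asterid1	asterid1.chr1	3	-m0011
asterid1	asterid1.chr1	4	m0005
asterid1	asterid1.chr2	1	m0001
asterid1	asterid1.chr2	2	m0005
asterid1	asterid1.chr3	1	m0001
asterid1	asterid1.chr3	2	m0006
asterid1	asterid1.chr3	3	m0005
asterid1	asterid1.chr4	1	-m0002
asterid1	asterid1.chr4	2	m0003
asterid1	asterid1.chr5	1	m0009
asterid1	asterid1.chr5	2	-m0008
asterid1	asterid1.chr5	3	-m0004
asterid1	asterid1.chr5	4	-m0010
asterid1	asterid1.chr5	5	-m0004
asterid1	asterid1.chr5	6	-m0007
asterid1	asterid1.chr5	7	-m0010
asterid1	asterid1.chr6	1	-m0012
asterid1	asterid1.chr6	2	m0008
asterid1	asterid1.chr6	3	-m0009
asterid1	asterid1.chr6	4	-m0004
asterid1	asterid1.chr6	5	-m0007
asterid1	asterid1.chr6	6	-m0010
asterid1	asterid1.chr6	7	m0009
asterid1	asterid1.chr6	8	-m0008
asterid1	asterid1.chr6	9	m0012
asterid2	asterid2.chr1	1	m0001
asterid2	asterid2.chr1	2	m0006
asterid2	asterid2.chr1	3	-m0011
asterid2	asterid2.chr1	4	m0005
asterid2	asterid2.chr2	1	m0001
asterid2	asterid2.chr2	2	-m0009
asterid2	asterid2.chr2	3	m0010
asterid2	asterid2.chr2	4	m0007
asterid2	asterid2.chr2	5	m0005
asterid2	asterid2.chr3	1	m0001
asterid2	asterid2.chr3	2	m0006
asterid2	asterid2.chr3	3	m0004
asterid2	asterid2.chr3	4	m0009
asterid2	asterid2.chr3	5	-m0008
asterid2	asterid2.chr3	6	m0012
asterid2	asterid2.chr4	1	-m0003
asterid2	asterid2.chr4	2	m0002
asterid2	asterid2.chr4	3	-m0004
asterid2	asterid2.chr4	4	-m0010
asterid2	asterid2.chr5	1	-m0004
asterid2	asterid2.chr5	2	-m0007
asterid2	asterid2.chr5	3	-m0010
asterid2	asterid2.chr5	4	m0009
asterid2	asterid2.chr5	5	-m0008
asterid2	asterid2.chr6	1	-m0005
asterid2	asterid2.chr6	2	-m0008
asterid2	asterid2.chr6	3	m0012
asterid3	asterid3.chr1	1	m0001
asterid3	asterid3.chr1	2	m0006
asterid3	asterid3.chr1	3	-m0011
asterid3	asterid3.chr1	4	m0005
asterid3	asterid3.chr1	5	-m0008
asterid3	asterid3.chr1	6	-m0012
asterid3	asterid3.chr2	1	m0001
asterid3	asterid3.chr2	2	m0005
asterid3	asterid3.chr3	1	m0001
asterid3	asterid3.chr3	2	m0006
asterid3	asterid3.chr3	3	m0005
asterid3	asterid3.chr4	1	-m0003
asterid3	asterid3.chr4	2	m0002
asterid3	asterid3.chr4	3	-m0004
asterid3	asterid3.chr4	4	-m0010
asterid3	asterid3.chr5	1	-m0004
asterid3	asterid3.chr5	2	-m0007
asterid3	asterid3.chr5	3	-m0010
asterid3	asterid3.chr5	4	m0009
asterid3	asterid3.chr5	5	-m0008
asterid3	asterid3.chr6	1	-m0009
asterid3	asterid3.chr6	2	m0007
asterid3	asterid3.chr6	3	m0004
asterid3	asterid3.chr6	4	-m0010
asterid3	asterid3.chr6	5	m0009
asterid3	asterid3.chr6	6	-m0008
asterid3	asterid3.chr6	7	m0012
asterid4	asterid4.chr1	1	m0001
asterid4	asterid4.chr1	2	m0006
asterid4	asterid4.chr1	3	-m0011
asterid4	asterid4.chr1	4	m0005
asterid4	asterid4.chr1	5	-m0008
asterid4	asterid4.chr1	6	m0012
asterid4	asterid4.chr2	1	-m0001
asterid4	asterid4.chr3	1	m0001
asterid4	asterid4.chr3	2	m0005
asterid4	asterid4.chr4	1	m0002
asterid4	asterid4.chr4	2	-m0004
asterid4	asterid4.chr4	3	-m0010
asterid4	asterid4.chr5	1	-m0003
asterid4	asterid4.chr5	2	-m0005
asterid4	asterid4.chr5	3	-m0001
asterid4	asterid4.chr5	4	m0001
asterid4	asterid4.chr5	5	m0006
asterid4	asterid4.chr5	6	m0005
asterid4	asterid4.chr6	1	-m0003
asterid4	asterid4.chr6	2	m0002
asterid4	asterid4.chr6	3	-m0004
asterid4	asterid4.chr7	1	-m0004
asterid4	asterid4.chr7	2	-m0007
asterid4	asterid4.chr7	3	-m0010
asterid4	asterid4.chr7	4	m0009
asterid4	asterid4.chr7	5	-m0008
asterid4	asterid4.chr8	1	-m0004
asterid4	asterid4.chr9	1	-m0004
asterid4	asterid4.chr9	2	-m0010
asterid4	asterid4.chr10	1	-m0005
asterid4	asterid4.chr10	2	-m0006
asterid4	asterid4.chr11	1	-m0009
asterid4	asterid4.chr11	2	-m0004
asterid4	asterid4.chr11	3	-m0007
asterid4	asterid4.chr11	4	-m0010
asterid4	asterid4.chr11	5	m0009
asterid4	asterid4.chr11	6	-m0008
asterid4	asterid4.chr11	7	m0012
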