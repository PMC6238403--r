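key	value	note
copies_copia	49	published results text: de novo copies assignable to a superfamily, Copia share
copies_belpao	217	published results text: de novo copies assignable to a superfamily, BEL/Pao share
copies_gypsy	1371	published results text: de novo copies assignable to a superfamily, Gypsy share
copies_total_stated	1637	published results text: total de novo copies assignable to a superfamily
families_cluster	249	published results text: families defined as clusters of structurally detected copies
families_orphan	239	published results text: orphan copies with a translatable RT/RNaseH domain
families_repbase	20	published results text: referenced families not recovered structurally
families_repeatmasker	216	published results text: families defined from genome-scan sequences
families_total_stated	724	published results text: total families across the nine genomes
clades_total_stated	31	published summary: clades defined across the three superfamilies
galea_total_stated	72	published results text: GalEa families, genomes plus databases
hydra_total_stated	43	published results text: Hydra families, genomes plus databases
sailor_total_stated	209	published results text: families clustered into the Sailor lineage
sinbad_total_stated	56	published results text: sensu stricto Sinbad families within Sailor
surcouf_total_stated	23	published results text: Surcouf families within Sailor
sparrow_text_stated	153	published results text; conflicts with the census table (70+60=130) and with the lineage total 209=130+56+23; not used for verification
tas_total_stated	92	published results text: Tas elements in molluscs
suzu_total_stated	31	published results text: Suzu elements in molluscs
abclade_total_stated	75	published results text: A-clade plus B-clade elements
molgy1_total_stated	139	published results text: MolGy1 elements
molgy2_total_stated	232	published results text: MolGy2 elements
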