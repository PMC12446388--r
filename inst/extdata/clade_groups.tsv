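# Representative taxa for the 26 taxonomic clade groups (class to infraorder)
# used to pool species in the comparative TRPA1 analysis. One to three
# representative taxa per group; the full species set is user-supplied.
taxon_id	group_id	group_name	superorder
Petromyzon_marinus	1	Cyclostomata	Agnatha
Carcharodon_carcharias	2	Chondrichthyes	Chondrichthyes
Polypterus_senegalus	3	Cladistei	Actinopterygii
Acipenser_ruthenus	4	Chondrostei	Actinopterygii
Lepisosteus_oculatus	5	Holostei	Actinopterygii
Danio_rerio	6	Teleostei	Actinopterygii
Oryzias_latipes	6	Teleostei	Actinopterygii
Takifugu_rubripes	6	Teleostei	Actinopterygii
Latimeria_chalumnae	7	Coelacanthi_Dipnoi	Sarcopterygii
Xenopus_laevis	8	Amphibia	Amphibia
Crotalus_atrox	9	Reptilia	Reptilia
Struthio_camelus	10	Palaeognathae	Aves
Gallus_gallus	11	Neognathae	Aves
Ornithorhynchus_anatinus	12	Monotremata	Prototheria
Monodelphis_domestica	13	Marsupialia	Metatheria
Trichechus_manatus	14	Sirenia	Afrotheria
Loxodonta_africana	15	Proboscidea	Afrotheria
Orycteropus_afer	16	Afroinsectiphilia	Afrotheria
Orcinus_orca	17	Cetacea	Laurasiatheria
Hippopotamus_amphibius	18	Hippopotamidae	Laurasiatheria
Bos_taurus	19	Ruminantia	Laurasiatheria
Sus_scrofa	20	Suina	Laurasiatheria
Zalophus_californianus	21	Pinnipedia	Laurasiatheria
Mustela_putorius	22	Musteloidea	Laurasiatheria
Ursus_maritimus	23	Ursidae	Laurasiatheria
Oryctolagus_cuniculus	24	Lagomorpha	Euarchontoglires
Mus_musculus	25	Rodentia	Euarchontoglires
Rattus_norvegicus	25	Rodentia	Euarchontoglires
Ictidomys_tridecemlineatus	25	Rodentia	Euarchontoglires
Homo_sapiens	26	Primates	Euarchontoglires
Macaca_mulatta	26	Primates	Euarchontoglires
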