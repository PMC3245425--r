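taxonID	scientificName	taxonRank	taxonomicStatus	parentNameUsageID	acceptedNameUsageID	vernacularName	language	distribution	datasetID	taxonConceptID	scientificNameID	namePublishedIn
a1	Plantae	kingdom	accepted									
a2	Fabales	order	accepted	a1								
a3	Fabaceae	family	accepted	a2								
a4	Abrus	genus	accepted	a3								
a5	Abrus precatorius L.	species	accepted	a4				pantropical	ildis			Syst. Nat. ed. 12, 2: 472 (1767)
a5s1	Abrus tunguensis	species	synonym		a5							
a5v1	Abrus precatorius L.	species	vernacular		a5	crab's eye	en					
a5v2	Abrus precatorius L.	species	vernacular		a5	rosary pea	en					
a5v3	Abrus precatorius L.	species	vernacular		a5	jequirity	en					
a6	Abrus precatorius subsp. africanus Verdc.	subspecies	accepted	a5								
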