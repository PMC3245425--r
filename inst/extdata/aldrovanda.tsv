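taxonID	scientificName	taxonRank	taxonomicStatus	parentNameUsageID	acceptedNameUsageID	vernacularName	language	distribution	datasetID	taxonConceptID	scientificNameID	namePublishedIn
v1	Plantae	kingdom	accepted									
v2	Nepenthales	order	accepted	v1								
v3	Droseraceae	family	accepted	v2								
v4	Aldrovanda	genus	accepted	v3								
v5	Aldrovanda vesiculosa L.	species	accepted	v4								
v5s1	Aldrovanda verticillata Roxb.	species	synonym		v5							
v5s2	Drosera aldrovanda F. Muell.	species	synonym		v5							
v5v1	Aldrovanda vesiculosa L.	species	vernacular		v5	waterwheel plant	en					
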