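taxonID	scientificName	taxonRank	taxonomicStatus	parentNameUsageID	acceptedNameUsageID	vernacularName	language	distribution	datasetID	taxonConceptID	scientificNameID	namePublishedIn
p1	Fungi	kingdom	accepted									
p2	Zoopagales	order	accepted	p1								
p3	Piptocephalidaceae	family	accepted	p2								
p4	Piptocephalis	genus	accepted	p3								
p5	Piptocephalis pseudocephala (Bainier) Benj.	species	accepted	p4					indexfungorum		urn:lsid:indexfungorum.org:names:145781	
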