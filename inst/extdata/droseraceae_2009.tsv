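taxonID	scientificName	taxonRank	taxonomicStatus	parentNameUsageID	acceptedNameUsageID	vernacularName	language	distribution	datasetID	taxonConceptID	scientificNameID	namePublishedIn
e1	Nepenthales	order	accepted									
e2	Droseraceae	family	accepted	e1								
e3	Aldrovanda	genus	accepted	e2								
e4	Aldrovanda vesiculosa L.	species	accepted	e3								
e4s1	Aldrovanda verticillata Roxb.	species	synonym		e4							
e4s2	Drosera aldrovanda F. Muell.	species	synonym		e4							
e5	Dionaea	genus	accepted	e2								
e6	Dionaea muscipula J.Ellis	species	accepted	e5								
e7	Drosera	genus	accepted	e2								
e8	Drosera anglica Huds.	species	accepted	e7								
e9	Drosera filiformis Raf.	species	accepted	e7								
e10	Drosera filiformis var. filiformis	variety	accepted	e9								
e11	Drosera filiformis var. tracyi	variety	accepted	e9								
e11s1	Drosera tracyi Macfarl.	variety	synonym		e11							
e12	Drosera rotundifolia L.	species	accepted	e7								
e13	Drosera rotundifolia var. rotundifolia	variety	accepted	e12								
e14	Drosera rotundifolia var. comosa	variety	accepted	e12								
e15	Drosophyllum	genus	accepted	e2								
e16	Drosophyllum lusitanicum (L.) Link	species	accepted	e15								
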