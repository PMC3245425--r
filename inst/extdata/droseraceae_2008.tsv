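taxonID	scientificName	taxonRank	taxonomicStatus	parentNameUsageID	acceptedNameUsageID	vernacularName	language	distribution	datasetID	taxonConceptID	scientificNameID	namePublishedIn
d1	Nepenthales	order	accepted									
d2	Droseraceae	family	accepted	d1								
d3	Dionaea	genus	accepted	d2								
d4	Dionaea muscipula J.Ellis	species	accepted	d3								
d5	Drosera	genus	accepted	d2								
d6	Drosera anglica Huds.	species	accepted	d5								
d7	Drosera filiformis Raf.	species	accepted	d5								
d8	Drosera filiformis var. filiformis	variety	accepted	d7								
d9	Drosera rotundifolia L.	species	accepted	d5								
d10	Drosera rotundifolia var. rotundifolia	variety	accepted	d9								
d11	Drosera tracyi Macfarl.	species	accepted	d5								
d11s1	Drosera filiformis var. tracyi	species	synonym		d11							
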