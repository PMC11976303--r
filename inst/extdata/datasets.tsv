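datasetID	datasetName
COL	Catalogue of Life
COLChina	Catalogue of Life China
GBIF	GBIF Backbone Taxonomy
LCVP	Leipzig Catalogue of Vascular Plants
POWO	Plants of the World Online
WFO	World Flora Online
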