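raw	standard
taxol	paclitaxel
abraxane	paclitaxel
paclitaxel	paclitaxel
oncovin	vincristine
vincristine sulfate	vincristine
vincristine	vincristine
camptosar	irinotecan
irinotecan hcl	irinotecan
irinotecan	irinotecan
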