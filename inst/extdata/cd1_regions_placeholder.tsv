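# Placeholder antigen-presenting-region windows on a CD1-like reference
# protein (synthetic coordinates, NOT authoritative domain annotations).
# Edit to match the reference query's real alpha1/alpha2 helix and
# beta-sheet boundaries before use.
name	start	end
alpha1_helix	60	90
alpha2_helix	140	175
beta_sheet_platform	5	55
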