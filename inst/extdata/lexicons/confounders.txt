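# Confounder phrases: non-service uses of military vocabulary.
# A military term whose match span lies inside one of these spans is
# suppressed (e.g. "army" inside "salvation army").
salvation army
salvation army hostel
military precision
military style
army of volunteers
army surplus
navy blue
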