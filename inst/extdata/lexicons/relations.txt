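# Relation words attributing military service to another individual.
father
mother
dad
mum
husband
wife
son
daughter
brother
sister
uncle
aunt
grandfather
grandmother
granddad
partner
boyfriend
girlfriend
cousin
nephew
niece
friend
neighbour
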