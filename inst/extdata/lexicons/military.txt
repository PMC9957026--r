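# Military terms and phrases indicating the patient's own service.
# One phrase per line; matching is token-boundary and case-insensitive
# after normalization. This list is a configurable data artifact seeded
# with service-branch names, rank words and service phrases.
veteran
army
navy
raf
royal air force
royal navy
royal marines
marines
armed forces
military
soldier
infantry
regiment
paratrooper
gunner
corporal
sergeant
ex serviceman
ex servicewoman
ex forces
ex military
served in the forces
served in the army
served in the navy
military service
national service
tour of duty
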