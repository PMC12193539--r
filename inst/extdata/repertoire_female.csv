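code,name,description,phase,terminal,notes
FW,Female walks,Walks on the periphery of the arena without apparent direction,premating,FALSE,
FQ,Female is quiet,Still with the head down,premating,FALSE,
FHMCA,Female moves head and antennae,Moves her head up and down and contracts and extends her antennae,premating,FALSE,
FTDM,Female turns in direction of male,Turns head and thorax towards the male,premating,FALSE,
FWDM,Female walks in direction of male,Walks straight toward the male occasionally extending her antennae,premating,FALSE,
FMA,Female moves away from male,Stops walking the periphery or moves away from the male,premating,FALSE,
FMM,Female meets the male,Female and male meet and interact,premating,FALSE,
FWK,Female walks kicking the male,Moves forward while thrusting back a hind leg against the grasping male pushing him backward,premating,FALSE,
FM,Female is in mounting,Walks with the male on top; his aedeagus is inserted in her pygidium,mating,FALSE,
FQHM,Female quiet with head movements,Stops and moves her head up and down stretching and contracting her antennae,mating,TRUE,
FWP,Female walks (postcopulatory),Walks with or without the male on top; the aedeagus is not inserted,postmating,TRUE,
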