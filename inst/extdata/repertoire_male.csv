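code,name,description,phase,terminal,notes
MW,Male walks,Walks along the periphery of the arena without apparent direction,premating,FALSE,
MQ,Male is quiet,Still with the head down,premating,FALSE,
MHAM,Male head movement and antennation,Moves antennae up and down with head movements and alternating antennal contraction and extension,premating,FALSE,
MTDF,Male turns in direction of female,Turns head and thorax towards the walking female,premating,FALSE,
MWDF,Male walks in direction of female,Changes course and walks directly toward the female,premating,FALSE,
MATFB,Male antennation on female's body,Touches the lateral thorax or abdomen of the female with his antennae,premating,FALSE,
MHFAR,Male holds female and antennal rubbing,Holds the female's elytra with his tarsi and rubs his antennae on her elytra,premating,FALSE,
MEE,Male extends aedeagus,Folds his abdomen and exposes the aedeagus,premating,FALSE,
MIE,Male introduces aedeagus,Inserts the aedeagus into the female's pygidium,mating,FALSE,
MM,Male mounting the female,Mounted with aedeagus inserted; rubs antennae on her elytra and occasionally moves the abdomen,mating,FALSE,
MG,Male guarding the female,On top of the female holding her with the foreleg tarsal claws; aedeagus neither inserted nor exposed; no antennal rubbing,postmating,TRUE,
MWP,Male walking (postcopulatory),Releases the female and walks away,postmating,TRUE,
MQP,Male quiet (postcopulatory),Still with the head down after release,postmating,TRUE,once-mated only
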