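name	class	start	end
signal peptide	signal_peptide	1	23
helix 1	helix	112	153
helix 2	helix	173	213
helix 3	helix	221	262
helix 4	helix	275	314
lipid binding 1	lipid_binding	24	169
lipid binding 2	lipid_binding	194	268
lipid binding 3	lipid_binding	316	366
RBD1	receptor_binding	21	26
RBD2	receptor_binding	36	43
RBD3	receptor_binding	48	54
RBD4	receptor_binding	90	98
RBD5	receptor_binding	146	152
RBD6	receptor_binding	182	190
RBD7	receptor_binding	232	237
RBD8	receptor_binding	251	257
RBD9	receptor_binding	281	292
heparin binding	heparin_binding	209	250
LPL activation	lpl_activation	215	261
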