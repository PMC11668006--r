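# Rule lexicons for the regex name classifier.
# One trigger per line; '#' starts a comment; matching is case-insensitive
# and whole-token ("dr" never fires inside "drug"). Trailing '.' or ':' in
# an entry is decoration: "dr." and "dr" match the same token.

[salutations]
dr
dr.
doctor
mr
mrs
ms
miss
prof
professor
sister
nurse
sir
madam

[labels]
name:
patient:
reporter:
physician:
doctor:
consultant:
signed:
contact:

[titles]
m.d.
md
ph.d.
phd
rn
mbbs
frcp
mrcp
bsc
msc
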