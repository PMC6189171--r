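gene	secreted	nuclear_only	itam_inaccessible	known_itam_receptor
gene01	FALSE	FALSE	FALSE	FALSE
gene02	TRUE	FALSE	FALSE	FALSE
gene03	FALSE	TRUE	FALSE	FALSE
gene04	FALSE	FALSE	TRUE	FALSE
gene05	FALSE	FALSE	FALSE	TRUE
gene06	TRUE	TRUE	FALSE	FALSE
gene07	FALSE	FALSE	FALSE	FALSE
gene08	FALSE	FALSE	TRUE	TRUE
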