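pair5	pair3	dG
AU	AU	-0.93
AU	UA	-1.10
AU	CG	-2.24
AU	GC	-2.08
UA	AU	-1.33
UA	UA	-0.93
UA	CG	-2.35
UA	GC	-2.11
CG	AU	-2.11
CG	UA	-2.08
CG	CG	-3.26
CG	GC	-2.36
GC	AU	-2.35
GC	UA	-2.24
GC	CG	-3.42
GC	GC	-3.26
AU	GU	-1.10
AU	UG	-1.10
UA	GU	-1.10
UA	UG	-1.10
CG	GU	-1.10
CG	UG	-1.10
GC	GU	-1.10
GC	UG	-1.10
GU	AU	-1.10
GU	UA	-1.10
GU	CG	-1.10
GU	GC	-1.10
UG	AU	-1.10
UG	UA	-1.10
UG	CG	-1.10
UG	GC	-1.10
GU	GU	-0.40
GU	UG	-0.40
UG	GU	-0.40
UG	UG	-0.40
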