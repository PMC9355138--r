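row_label,col_label,value,marker
IBase.Alternative,IBase.Alternative,0.78,omega
IBase.Country,IBase.Country,0.77,omega
IBase.HipHop,IBase.HipHop,0.48,omega
IBase.Mainstream,IBase.Mainstream,0.44,omega
IBase.Popular,IBase.Popular,0.45,omega
VMLS.Alternative,VMLS.Alternative,0.70,omega
VMLS.Country,VMLS.Country,0.77,omega
VMLS.HipHop,VMLS.HipHop,0.56,omega
VMLS.Mainstream,VMLS.Mainstream,0.61,omega
VMLS.Popular,VMLS.Popular,0.59,omega
IBase.Country,IBase.Alternative,-0.60,***
IBase.HipHop,IBase.Alternative,-0.23,***
IBase.HipHop,IBase.Country,-0.25,***
IBase.Mainstream,IBase.Alternative,-0.23,***
IBase.Mainstream,IBase.Country,-0.14,***
IBase.Mainstream,IBase.HipHop,-0.27,***
IBase.Popular,IBase.Alternative,-0.59,***
IBase.Popular,IBase.Country,-0.01,ns
IBase.Popular,IBase.HipHop,0.09,**
IBase.Popular,IBase.Mainstream,0.05,ns
VMLS.Alternative,IBase.Alternative,0.53,***
VMLS.Alternative,IBase.Country,-0.40,***
VMLS.Alternative,IBase.HipHop,-0.06,*
VMLS.Alternative,IBase.Mainstream,-0.03,ns
VMLS.Alternative,IBase.Popular,-0.32,***
VMLS.Country,IBase.Alternative,-0.30,***
VMLS.Country,IBase.Country,0.55,***
VMLS.Country,IBase.HipHop,-0.12,***
VMLS.Country,IBase.Mainstream,-0.14,***
VMLS.Country,IBase.Popular,-0.03,ns
VMLS.Country,VMLS.Alternative,-0.38,***
VMLS.HipHop,IBase.Alternative,-0.17,***
VMLS.HipHop,IBase.Country,0.08,**
VMLS.HipHop,IBase.HipHop,0.17,***
VMLS.HipHop,IBase.Mainstream,-0.08,*
VMLS.HipHop,IBase.Popular,0.11,***
VMLS.HipHop,VMLS.Alternative,-0.36,***
VMLS.HipHop,VMLS.Country,-0.05,ns
VMLS.Mainstream,IBase.Alternative,-0.02,ns
VMLS.Mainstream,IBase.Country,-0.07,*
VMLS.Mainstream,IBase.HipHop,-0.13,***
VMLS.Mainstream,IBase.Mainstream,0.23,***
VMLS.Mainstream,IBase.Popular,0.06,*
VMLS.Mainstream,VMLS.Alternative,-0.22,***
VMLS.Mainstream,VMLS.Country,-0.26,***
VMLS.Mainstream,VMLS.HipHop,-0.23,***
VMLS.Popular,IBase.Alternative,-0.19,***
VMLS.Popular,IBase.Country,-0.04,ns
VMLS.Popular,IBase.HipHop,0.18,***
VMLS.Popular,IBase.Mainstream,-0.02,ns
VMLS.Popular,IBase.Popular,0.26,***
VMLS.Popular,VMLS.Alternative,-0.28,***
VMLS.Popular,VMLS.Country,-0.19,***
VMLS.Popular,VMLS.HipHop,-0.17,***
VMLS.Popular,VMLS.Mainstream,-0.28,***
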