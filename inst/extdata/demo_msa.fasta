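>b2ar_human|B2
DRYFAITSPF
>b1ar_human|B1
DRYLAITSPF
>d2r_human|D2
DRYTAVAMPM
>d3r_human|D3
DRYTAVVMPV
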