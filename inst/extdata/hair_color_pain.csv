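pain_tolerance,hair_color
62,LightBlond
60,LightBlond
71,LightBlond
55,LightBlond
48,LightBlond
63,DarkBlond
57,DarkBlond
52,DarkBlond
41,DarkBlond
43,DarkBlond
42,LightBrunette
50,LightBrunette
41,LightBrunette
37,LightBrunette
32,DarkBrunette
39,DarkBrunette
51,DarkBrunette
30,DarkBrunette
35,DarkBrunette
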