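group,genotypes
1,1-2-3-4-5-6-7-8-10-11-12-13-15-16-18-20-21-23-24-25-26-27-28-29-30-31-32-33-34-35-36-37-38
2,9
3,14
4,17
5,19
6,22
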