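group,genotypes
I,1-5-11-13-20-21-22-27-28-29-31-35-36-37
II,2-3-6-8-10-12-32
III,24-25-26
IV,4-7-18-30
V,15-16-38
VI,14
VII,23
VIII,17
IX,19
X,33
XI,9
XII,34
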