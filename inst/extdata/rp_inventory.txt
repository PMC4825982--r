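iː
ɪ
e
æ
ʌ
ɑː
ɒ
ɔː
ʊ
uː
ɜː
ə
eɪ
aɪ
ɔɪ
əʊ
aʊ
ɪə
eə
ʊə
p
b
t
d
k
ɡ
tʃ
dʒ
f
v
θ
ð
s
z
ʃ
ʒ
h
m
n
ŋ
l
r
w
j
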