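;;; Miniature RP-style English pronunciation lexicon (fixture).
;;; One entry per line: WORD<TAB>PH1 PH2 ... ; 44-symbol inventory.
the	ð ə
a	ə
and	æ n d
to	t uː
of	ɒ v
it	ɪ t
it's	ɪ t s
is	ɪ z
in	ɪ n
i	aɪ
you	j uː
he	h iː
she	ʃ iː
was	w ɒ z
that	ð æ t
row	r əʊ
low	l əʊ
boat	b əʊ t
ship	ʃ ɪ p
sheep	ʃ iː p
cat	k æ t
dog	d ɒ ɡ
bird	b ɜː d
house	h aʊ s
mouse	m aʊ s
boy	b ɔɪ
toy	t ɔɪ
day	d eɪ
night	n aɪ t
light	l aɪ t
ear	ɪə
air	eə
tour	t ʊə
book	b ʊ k
food	f uː d
good	ɡ ʊ d
father	f ɑː ð ə
mother	m ʌ ð ə
brother	b r ʌ ð ə
water	w ɔː t ə
thing	θ ɪ ŋ
think	θ ɪ ŋ k
this	ð ɪ s
measure	m e ʒ ə
vision	v ɪ ʒ ə n
church	tʃ ɜː tʃ
judge	dʒ ʌ dʒ
yes	j e s
no	n əʊ
go	ɡ əʊ
see	s iː
say	s eɪ
said	s e d
man	m æ n
men	m e n
woman	w ʊ m ə n
child	tʃ aɪ l d
children	tʃ ɪ l d r ə n
time	t aɪ m
year	j ɪə
hand	h æ n d
word	w ɜː d
world	w ɜː l d
about	ə b aʊ t
there	ð eə
here	h ɪə
poor	p ʊə
girl	ɡ ɜː l
white	w aɪ t
red	r e d
green	ɡ r iː n
blue	b l uː
one	w ʌ n
two	t uː
three	θ r iː
love	l ʌ v
have	h æ v
has	h æ z
had	h æ d
not	n ɒ t
all	ɔː l
call	k ɔː l
car	k ɑː
far	f ɑː
more	m ɔː
door	d ɔː
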