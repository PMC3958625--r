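# Pinned public-suffix table (offline snapshot, one suffix per line).
# Registrable-domain reduction matches the longest listed suffix against the
# tail of a host; the registrable domain is one label plus that suffix.
com
org
net
edu
gov
mil
int
info
biz
name
io
co
tv
me
eu
de
uk
fr
it
nl
ch
at
us
ca
au
jp
nz
br
za
ru
pl
se
no
fi
dk
es
pt
cz
gr
hu
ie
be
example
co.uk
org.uk
ac.uk
gov.uk
me.uk
net.uk
com.au
net.au
org.au
edu.au
gov.au
co.nz
org.nz
net.nz
ac.nz
co.jp
ne.jp
or.jp
ac.jp
com.br
org.br
net.br
co.za
org.za
ac.za
com.mx
org.mx
com.ar
com.cn
net.cn
org.cn
co.in
net.in
org.in
ac.in
co.kr
or.kr
com.tr
org.tr
com.sg
edu.sg
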