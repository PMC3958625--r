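domain	class
youtube.com	Social
facebook.com	Social
twitter.com	Social
blogspot.com	Social
wordpress.com	Social
wikipedia.org	Scientific
nih.gov	Scientific
nature.com	Scientific
sciencedirect.com	Scientific
dmsg.de	Organization
msif.org	Organization
nationalmssociety.org	Organization
spiegel.de	News
bbc.co.uk	News
nytimes.com	News
amazon.com	Commerce
ebay.com	Commerce
mayoclinic.org	HealthcareProviders
charite.de	HealthcareProviders
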