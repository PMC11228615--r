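>REF_A1a type=A1 primary=yes synthetic=yes
WPRGMTLKGMDQHYRRYSIQGRVGIYYTHEVCTTLNQSIDFILCVTFLDFFAFWVAVTTQMMMCEKGWPAPDYTWPFKDRSSGVFFVHNSVDEWSKHRATPNQSMDWQANMSFVSDKANQITRTDSTYEGTNASCGSNPPFFESIKHMCFMKKWPQLLFGTGAVGSVGTNMNYYSVTHEHNWYYGIYLITRPCGANRNAGASWYPHALGESARWVKLFGIMLQILIRGFPLICIHCCGWDKTTRAAPDLYYWMHLAPALENSKYLHWYVWFTWLKCQRQGAKGMVADDGLAWFQGDIVWGMIDLIYFTTALARWDGIEPDFIAKIGQSNCAWIEVTEHPDECVRLTNHFPTHVPKWCGMMDFRRWDGQQLDLRAHACALG
>REF_A1b type=A1 synthetic=yes
WPRGMTLKGMDQHYRRYSIQGRVGIYYTHEVCTTLNQSIDFILCVTFLWFFAFWVAVTTQMMMCEKGWPAPDYTWPFKDRSSGVFFVHNSVDEWSEHRATPNQSMDWQANMSFVSDTAYQITYTDSTGEGTNASCGNNPPRFEKIKHMCFMKMWPQLLFGTGAVGSVGTEMNYYSVTHMHNWYYGIYLITRPCGANRNAGASWYPHALGESARWVKLFGIMLQILIRGFPLICIHCCGWDKTTRAAPDLYYWDHLAPALERSKYLHWYVWFTWLKCQRMGAKGVVADDGLAWFQGDIVWGMIDLIYFTTALARWDGIEPDFIAFIAQSNCQWVEVTEHPDECVRLTNHMPTHVPKWCGMMDFRDWDGQQLDLRAHACAQG
>REF_A2 type=A2 synthetic=yes
WPRGMTLKGMDQHYNRSSIEGRYGHYYTHEVCTTLNQSIDFILCVTFLDFKAFWVAVTTQMMMCEKGWPAPDYTWYFKDRSSGVFFVHNSVDEWSKHRATPNQSDDWQANMSFVSDKANQITRTDSTYEGTNASCGSNPPFFESIKHMCFMKKWPQLLFGTGAVGSVGTNMNYYSVTDEHNWYYGIYLITRPCIANRNALAAWYPHALGESARYVKLFGIMLQILIRGFPLICIHCCGWDKTTRAAPDLYYWMHLAPHLENSKYLTWYVWFTWLKCQRWGAKGMVADDGLAWFQGDIRWAAIDLIYFTTALARWDGIEPDFIAKIGQSNCAWIEVTEHPDECVRLTNHFPTHVPKWCGMMDFRRWDGQQLDLRAHACALG
>REF_B1a type=B1 synthetic=yes
WPRGMTLQGMDQHYRRFSIQGRVGIYYTNAVCTTLNQSIDFILCVTFLDFFAFWVAVTTQMMMCEKGWPAPDYTWPFGDRSSGVFFVHNSVDEWSKHRATPNQSMDWQFPMSFVSDKAKQITRTDSTYEGTNASCGYNPPFFESIKHMCFMKKWPQLLFGTGSVGSVGTNMNYYSVTHEHNWYYGIYLITRQCGANRNALDDWYPHALGRWARWVKLFGIMTQILIRGFPLICIHCCGWSKTTRAAPDLYYGMHLAPALENSKYLHWYVWFTWLKCQRQGAKGMVADDGLAWFQGDIVWGMIDPIYFTTRLARWDGIEPDFIAKIGQSNCAWIEVTEHPDECVRLTNHFPQHVPKWCNMMDFRRWDGQQLDLRAHACAKG
>REF_B1b type=B1 synthetic=yes
WPRGMTLKGMDQHYRRYSIQGVVGIYYTHEVCITLNQSVDFILCVTFLDFFAFWVAVTTQMMMCEKGWPAPDYTWPFKDRSSGPFFVHNSVDEWSKHRAYPNQSMDWQANMSFVSDKANQITRTDSTYEGTNASCGSNPPFFESIKHMCFMKKWPQLLFGTGAVGSVGTNMNYYSVTHEHKWYYGIYKITRPCGANRDALDDWYPHALGRSARWVKLFGIMTQILIRGFPLICIHCCGWSKTTRAAPDQYYGMHLAPALENSKYLHWYVWCTWLKCQRQGIKGMVADDGLALFQGDIVWGMITLIYFTTRLARWDGISPDFIAKIGQSNCAWIELTEHPDECVRLTNHFPTHVPKWCGMMDFRRWDGQQLDLRAHACALG
>REF_B2 type=B2 synthetic=yes
WPRGMTLKGMDQHYRRYSIQGRVGIYYTHEVCTTLNQSIDFILCVEFLDLFAFWVAVTTTMMMCEKGWPAPDYTWPFKVRSSGVFFVHNSVDEWSKHRATPNQSMDWQANMSFVSDKANQITRTDSTYEGTNASCGSNPPFFESIKHMVFMKKMPQLLFGGGAQGSVGTNMNYYSVYHEHNWYYGIYLITRPCGANRNALDDWDPHALGQSARWVKLFGIMTQILIRGFPLICIHCCGWSKTTRAAPDLYYGMHLAPALENSKYLHWYVRFTWPKCQVQGAKGMVADDGLAWFQGDIVWGMIDLIYFTTRLARWDGIEPHFIAKIGDSNCAWIEVTEHPDECVRFTNHFPTHVPKWCGMMDFRRWDGQQLDLRAHACALG
>REF_C1 type=C1 synthetic=yes
WPRGMTLKGWDQHYRRYSIQGRVGIYYTHEVCTTLNQSIDFILCQTFLDFFAFWVAVTTQMMMCEKGWPAPDYTWPFKDESSGVFFVQNSVDEWSKHRETPNQSMDWQANMSFVSDKANQPTRTDKNYEGMNASCGSNPPFFESIKHMCFMKKWPQLLFETEAVETVGTNMTYYSVTHEHNWYYEIYIITRPCGANRNAGASWYPHALGESARWVALFGIMVQILIRGFPLICIHCCGWSKTTRAAPDLYYGMHLAPALENSKYLVWFVWFEWLKRQRQGAKGMVADDGLAWFQGDIVFGMIDLIYFTTALARWDGIEPDFIAKIGQSNCCWIEVTEHPDECVRLTNHFPTHVPKNCGMMDFRRWDGQQLDLRAHACALC
>REF_C2 type=C2 synthetic=yes
EPRGMTLKGMDQHYRRYSIQGRVGIYYTHEVCTTLNQSIDFILCVTFLDFFAFWVAVTTKMMMCEKGWPAPDYTWPFKDRSSGVFFVHNSVDEWSKHRATPNQSMDWQANMSFVSDKANQHTRTLSTYEGTNASCGSNPPFRESIKHMCFMKKWPQLLFETEACESVGDNMNYYSVIHEHNWYYEIYLILRPCGANRNALDDWYPHALGQSARWVKLFGIVTAILIRGFPLICIHCCGWSKTDRAAPDLYYGMHLAPALENSDYLHWYVWFTWPKCQRQGAKGMVADDGLAWFQGDIVWGMIDLIYFMTRLAREDGIEPHFVAKIGQSNHAWIEVTEHPDECVRLTNHFPTHVPKWCGMMDFRRWDGQQLDLRAEACALG
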