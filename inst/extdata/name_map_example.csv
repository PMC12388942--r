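raw,generic
aspirin,acetylsalicylic acid
aspirin.,acetylsalicylic acid
asa,acetylsalicylic acid
acetylsalicylic acid,acetylsalicylic acid
advil,ibuprofen
motrin,ibuprofen
ibuprofen,ibuprofen
aleve,naproxen
naprosyn,naproxen
naproxen,naproxen
voltaren,diclofenac
diclofenac sodium,diclofenac
diclofenac,diclofenac
celebrex,celecoxib
celecoxib,celecoxib
vioxx,rofecoxib
rofecoxib,rofecoxib
mobic,meloxicam
meloxicam,meloxicam
indocin,indometacin
indomethacin,indometacin
indometacin,indometacin
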