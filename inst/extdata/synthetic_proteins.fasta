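>SYNPROT001
YDPILIGIHNHCVKSWYGRPTTYDNKYLVSVKRCVCGYQKLCCALAWQAQIITCSRFHNR
ATPVFHCVRGCEGMFSCN
>SYNPROT002
PFKQTPGDKSFEGVVETCDVSDEGRWYINCQVTMNNCKQVKLPPSCKYAGSYQQYWETQE
DMTSVFYHESITKRCTFCERYPQFNMIEFSLLM
>SYNPROT003
EPKMYTRRPKKCTMSLEMRPNTESSWNWLFLAMHHNQIDMVCPKNWMFNAIVFCGKFICA
VDWPLDPDGNMFEMCYIFHNCTENPSEIY
>SYNPROT004
EWDCCLMGRSNTCDKSLEGAPNTICWSIKIDTQECMLDIWYKCFIIEAMDGYHYALKEHP
YKVSTYCFKRMNICVHLDTKCCAKYL
>SYNPROT005
DFSMRAMMPRHYSSLVGRPNKCDHYLEGPPNTPVDAFDWNRGSMAYPDCCNQLWEAHDKE
GSEFHTLDEMACVNDMIRNNNLYCLGDMRYKW
>SYNPROT006
MEVRDLKRRDKSFCQRPPTCDDSLERRPTWMPYFTGPVEWMWGDCAMVLMFTICFCEFNV
EWPEHFTGINIFHKPVYVEQRCYMHWGTQCLDCNNGSANFTRG
>SYNPROT007
IYFREEDYHWLMSLEGRENTCKDSAEGDPNTGYRQGMAAMSIVLAVMNIDMMHTINCMTF
LNMNRKVEGMIMPGSFRHLSCMIGGGPSENWIEP
>SYNPROT008
NRMKAVKWRGGRPNTCDLTLPGLPNPMTDKDEGHHKMWSAIVEESNQEWVCCSNYYMTNG
SSFHIPWWKSTSCKHDRFQEKIVLLQLAAYDMIR
>SYNPROT009
WWKSWCGRLVTCDKSLEGRPYWSECRRYLLNLDKFSCYYCTAQRKDREHQDWKRCPHKEV
EYWFNNFNGCHNFYMQSQYDNGQ
>SYNPROT010
CCAGDKSLEGRPNTCFCSMNGRPNTVFNTHLRCPYLYACRHGIWDFMIVCVLREMYPYTQ
TYFFCDVVHLQKKYKSRDCLCPYIGNEKIY
>SYNPROT011
TTAPGETAAEQWDKSLEWTWLTCDKSMEGRPKTSPDILISKQQVRRLRCCVDYDFTGLLQ
DFHKSELCMTMGCWEHWTDVWEEDMCVDVNMCPS
>SYNPROT012
VLPFFFVEDMSREGRPNTCDATCEGRPNVMDYIKQSFPVACVGCERHVQNCHCWDKRWGK
QPCMYGRYCEELCAKSSCYNRCYTNHNNDYPD
>SYNPROT013
QDLQVKTWDKVKEGNMNCCETSLPMRLNTSSCMPHDKNHYLSFGCILCEWCAVNYMNVNL
ILCGEKRLDCRWWDCLAMAMGSTLML
>SYNPROT014
PRIDCFLEQRPNFCDPTMEGFWATVNILCVCRPIAVQEWPCTCHTVNQMPELTAHVRTFT
STIDRCCQHKYRSSGLPPYKH
>SYNPROT015
GDGFLIGRMNTCDKIKDGRPNTTEPKRKVAMDEWSWYMDSHIKIDPTCNHLWYNTTVYQG
WYPRDGNNTHRPLWEISNFRCEHSCELPFNVM
>SYNPROT016
LHDWEINKSLEGRPATCRKSIEGRPNTGNCNKCPLQDRIFGKRCFLHIEHEMSDVKMATM
AHFTWIYCYVKRHAEIQGPKQ
>SYNPROT017
WQWYPSKDWSLEGRFNTCIDSLEGLPNPMVINTFAANEPCACPSFHCLKRQSIEDACKRP
HCLQCREYEPHPASLCMRMHNSTVIWRFAFFQSY
>SYNPROT018
HLVFFNFLCGRDKTCDKSLAKRPKTTLHAHENRKEADCQFPEVIMFNMTCFENNCFPTRT
EPSCLADNKKIASTRRYEAADVT
>SYNPROT019
ICIFDKSYMGRATTCEKSLEGTPNLFACSNKMAMASRMDTICQEFQCFKGVCFYTVHELK
ENSEKGWEVVCTHFDSCMKQEDRTKTVLDWHIVPR
>SYNPROT020
GQMPVMDMPTKNLEQTPNTCDKSLEGRPNIPYGVIFNFGAFAYGKDWCAPPSPFNMYMDY
ILKRPFIPTWSLCYEADVCKLANQIEARCNPNNPDDWPVP
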