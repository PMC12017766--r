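>IGHV1-2|Homo sapiens|heavy|V
QVQLVQSGAEVKKPGASVKVSCKASGYTFTSYGISWVRQAPGQGLEWMGWISAYNGNTNYAQKLQGRVTMTTDTSTSTAYMELRSLRSDDTAVYYCAR
>IGHV1-40|Homo sapiens|heavy|V
PVQLVQSGAEVKKPGAYVKVSCKASGYTFTSYGISWVRQPPGQDLEMMTWISAYVGNTNYAQALQGRVTMTTDDSTSTAYMELPSNRSDDTADYYCAR
>IGHV1-93|Homo sapiens|heavy|V
CVQLVQSQAEVGKYGASVKISCLAIGVTVKSYGASWVRQNPGQGLEWMGWISAYNGCTNHAQKVQGRVTMTTYTRTSTNYMELRRLRSDDTFVYYCAR
>IGHV3-23|Homo sapiens|heavy|V
EVQLVESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK
>IGHV3-55|Homo sapiens|heavy|V
EVQIVESGGGLVGPGGTLRLSCAASGFTFSSYCMSWVRQAPGKGLEGVSAISGSGGSTYYADSVTDSFRISRDNHKNTLYLQMNFLRAEDTAVNYCAK
>IGHV3-89|Homo sapiens|heavy|V
EVQLVESGGGLVQPVGSLRPSCAYSGVFFRSFAMSWVRQANGKGLEWISAILYSGGLTYFADSVKGRLTISRQNSKNQPYLQMNSLRFEQTAVGYCAK
>IGHV5-51|Homo sapiens|heavy|V
EVQLVQSGAEVKKPGESLKISCKGSGYSFTSYWIGWVRQMPGKGLEWMGIIYPGDSDTRYSPSFQGQVTISADKSISTAYLQWSSLKASDTAMYYCAR
>IGHV5-65|Homo sapiens|heavy|V
EAQLVQSGAEVKKPGESLKISCKGSGCSFTSYWIGWVLQYPGKGLEWMGIIYPGDSDMRYSPSDDGQVSISIAKSCSTAELQWSSLKASDTAMYYCAR
>IGHV5-96|Homo sapiens|heavy|V
EVQVVDSPAEQKKPGESLQISCKVSGYAFCSVWIGWVRQMPGKGLEWMGIIMPGDSDTRYVPPFQGNDTIMEMKSITTAYLQWSSLKASFTAMYYCTR
>IGHV7-4|Homo sapiens|heavy|V
QCSENQSHAEMKKMGASVKVSCKASQTTFTSHACNWVRSAPGQGLGWMGWITPYNGNGNYAQTLQGRPTMTTDTQTSTAYDFLNSLRLSDTQVARCAR
>IGKV1-39|Homo sapiens|kappa|V
DIQMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIYAASSLQSGVPSRFSGSGSGTDFTLTISSLQPEDFATYYCQQSYSTP
>IGKV1-33|Homo sapiens|kappa|V
DIQMTQSPSSLSASVGDRVTITCRALQSISSYCNFYQQKPGYAPKLLIYAAKSLQSGASHRFSGSGSHTDFTLTISSLQPEDFATYYCQQHYSTM
>IGKV2-28|Homo sapiens|kappa|V
FIQMCQSRSSLSASVGERVVITRKASQSIMSYLGWYQQERGKTPKLGIYAASSFQAGVQSTFDGSGSDTDFTLTISSLQREDQATYYCQQNYETT
>IGKV4-1|Homo sapiens|kappa|V
DIVMTQSPDSLAVSLGERATINCKSSQSVLYSSNNKNYLAWYQQKPGQPPKLLIYWASTRESGVPDRFSGSGSGTDFTLTISSLQAEDVAVYYCQQYYSTP
>IGKV4-2|Homo sapiens|kappa|V
DIVMTQSPDSYAVSLGERATINCKSSQTVLYSQNNKKYLTWSQQKEGQPPKLLIYWASTREGGVPDRNSGSGSGTDFTLTISSLDAEDMAQYYCQQYYSTP
>IGKV3-20|Homo sapiens|kappa|V
DIVMTQSPDSLAPQLGEPATQNCKSSNSVLGSSPCKYMLAWYQQHHEQPPKLFIYWCSTRECGVPDRFVASGSGRSVTLTISSLQDEDVATYYCQLEYSTP
>IGLV1-40|Homo sapiens|lambda|V
QSVLTQPPSVSGAPGQRVTISCTGSSSNIGAGYDVHWYQQLPGTAPKLLIYGNSNRPSGVPDRFSGSKSGTSASLAITGLQAEDEADYYCQSYDSSLSG
>IGLV1-44|Homo sapiens|lambda|V
QSVNTQPTSVSGSPGQRVTISCTGSSSNIGAGYDVHIYQQLPETAPKLLDYGNSSRPSGVPDRFSGSKSIGAAMLAITGLQAEDEADYYCQSYDSSLIG
>IGLV2-14|Homo sapiens|lambda|V
QSVLTLPPSVSIAPHGRETISCTGSSSNIGGGYDVHWYQGLALTAPHLLIYGCSNRPSGELDRFCGSKSGISTNLALTGSQAEDERDYICQSYDSSLSP
>IGLV3-21|Homo sapiens|lambda|V
KSVLTSPPSVSGAPSQEVHIFCTESESNEGAGFHVHTYQQRRGTISKALIKILSNRPSGMPDRFSGSYSGTSAALAITGFVAEVEADYVCFSYTSSLSN
>IGHJ3|Homo sapiens|heavy|J
DAFDIWGQGTMVTVSS
>IGHJ4|Homo sapiens|heavy|J
YFDYWGQGTLVTVSS
>IGHJ6|Homo sapiens|heavy|J
YYYYYGMDVWGQGTTVTVSS
>IGKJ1|Homo sapiens|kappa|J
WTFGQGTKVEIK
>IGKJ2|Homo sapiens|kappa|J
YTFGQGTKLEIK
>IGLJ2|Homo sapiens|lambda|J
VVFGGGTKLTVL
>IGLJ3|Homo sapiens|lambda|J
WVFGGGTKLTVL
>IGHG1_CH1|Homo sapiens|heavy|C
ASTKGPSVFPLAPSSKSTSGGTAALGCLVKDYFPEPVTVSWNSGALTSGVHTFPAVLQSSGLYSLSSVVTVPSSSLGTQTYICNVNHKPSNTKVDKKV
>IGKC|Homo sapiens|kappa|C
RTVAAPSVFIFPPSDEQLKSGTASVVCLLNNFYPREAKVQWKVDNALQSGNSQESVTEQDSKDSTYSLSSTLTLSKADYEKHKVYACEVTHQGLSSPVTKSFNRGEC
>IGLC2|Homo sapiens|lambda|C
GQPKAAPSVTLFPPSSEELQANKATLVCLISDFYPGAVTVAWKADSSPVKAGVETTTPSKQSNNKYAASSYLSLTPEQWKSHRSYSCQVTHEGSTVEKTVAPTECS
>ANTIGEN_SYN|Homo sapiens|none|sink
IYERPGNGPGKYVGWPQSDLQRDQLGTFDNMHGMPHRKGIFGSWCQNHSGSWWGQIMEKQDSTLMKWATAKLSRHTGHHVFLVGWNWMWLRVRWGCTSHPLGLMKRVAMDIEKMEYDITQ
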