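status,family,species,growth_form,classification,pre_score,source
invasive,Aizoaceae,Carpobrotus chilensis,Perennial dicot,Needs Further Evaluation,13,printed
invasive,Aizoaceae,Carpobrotus edulis,Perennial dicot,Reject,17,printed
invasive,Aizoaceae,Mesembryanthemum crystallinium,Perennial dicot,Reject,20,printed
invasive,Anacardiaceae,Schinus terebinthifolius,Tree/shrub,Reject,18,printed
invasive,Apocynaceae,Vinca major,Shrub,Reject,16,printed
invasive,Araliaceae,Hedera canariensis,Shrub,Reject,16,printed
invasive,Araliaceae,Hedera helix,Shrub,Reject,18,printed
invasive,Asteraceae,Acroptilon repens,Perennial dicot,Reject,15,printed
invasive,Asteraceae,Ageratina adenophora,Perennial dicot,Reject,15,printed
invasive,Asteraceae,Arctotheca calendula,Perennial dicot,Reject,14,printed
invasive,Asteraceae,Centaurea calcitrapa,Perennial dicot,Reject,18,printed
invasive,Asteraceae,Centaurea solstitialis,Annual dicot,Reject,20,printed
invasive,Asteraceae,Cirsium vulgare,Biennial dicot,Reject,19,printed
invasive,Asteraceae,Glebionis coronarium (= Chrysanthemum coronorium),Annual dicot,Reject,15,printed
invasive,Asteraceae,Leucanthemum vulgare,Perennial dicot,Reject,20,printed
invasive,Brassicaceae,Brassica tournefortii,Annual dicot,Reject,17,printed
invasive,Brassicaceae,Cardaria pubescens,Perennial dicot,Reject,16,printed
invasive,Brassicaceae,Lepidium latifolium,Perennial dicot,Reject,20,printed
invasive,Buddlejaceae,Buddleja davidii,Shrub,Reject,18,printed
invasive,Chenopodiaceae,Halogeton glomeratus,Annual dicot,Reject,15,printed
invasive,Chenopodiaceae,Salsola tragus,Annual dicot,Reject,19,printed
invasive,Clusiaceae,Hypericum perforatum,Perennial dicot,Reject,18,printed
invasive,Elaeagnaceae,Elaeagnus angustifolia,Tree,Needs Further Evaluation,13,printed
invasive,Fabaceae,Acacia dealbata,Tree/shrub,Reject,18,printed
invasive,Fabaceae,Cytisus scoparius,Shrub,Reject,21,printed
invasive,Fabaceae,Cytisus striatus,Shrub,Reject,18,printed
invasive,Fabaceae,Gleditsia triacanthos,Tree,Needs Further Evaluation,13,printed
invasive,Fabaceae,Retama monosperma,Shrub,Needs Further Evaluation,12,printed
invasive,Fabaceae,Spartium junceum,Shrub,Reject,21,printed
invasive,Geraniaceae,Geranium robertianum,Perennial dicot,Reject,18,printed
invasive,Iridaceae,Iris pseudacorus,Perennial monocot,Reject,15,printed
invasive,Lamiaceae,Marrubium vulgare,Perennial dicot,Reject,16,printed
invasive,Lamiaceae,Mentha pulegium,Perennial dicot,Reject,18,printed
invasive,Moraceae,Ficus carica,Tree,Reject,19,printed
invasive,Myoporaceae,Myoporum laetum,Tree/shrub,Reject,17,printed
invasive,Pittosporaceae,Billardiera heterophylla (= Sollya heterophylla),Perennial vine/shrub,Reject,17,printed
invasive,Poaceae,Arundo donax,Perennial grass,Reject,14,printed
invasive,Poaceae,Brachypodium sylvaticum,Perennial grass,Reject,18,printed
invasive,Poaceae,Cortaderia jubata,Perennial grass,Reject,20,printed
invasive,Poaceae,Cortaderia selloana,Perennial grass,Reject,20,printed
invasive,Poaceae,Cynodon dactylon,Perennial grass,Reject,20,printed
invasive,Poaceae,Ehrharta calycina,Perennial grass,Reject,16,printed
invasive,Poaceae,Festuca arundinacea,Perennial grass,Reject,18,printed
invasive,Poaceae,Pennisetum clandestinum,Perennial grass,Reject,20,printed
invasive,Poaceae,Pennisetum setaceum,Perennial grass,Reject,18,printed
invasive,Poaceae,Piptatherum miliaceum,Perennial grass,Reject,17,printed
invasive,Poaceae,Saccharum ravennae,Perennial grass,Reject,18,printed
invasive,Pontederiaceae,Eichhornia crassipes,Perennial monocot,Reject,19,printed
invasive,Ranunculaceae,Ranunculus repens,Perennial dicot,Reject,14,printed
invasive,Rosaceae,Cotoneaster franchetii,Shrub,Reject,16,printed
invasive,Rosaceae,Cotoneaster pannosus,Shrub,Reject,16,printed
invasive,Rosaceae,Crataegus monogyna,Tree,Reject,16,printed
invasive,Scrophulariaceae,Linaria vulgaris,Perennial dicot,Reject,21,printed
invasive,Scrophulariaceae,Verbascum thapsus,Biennial dicot,Reject,16,printed
invasive,Solanaceae,Nicotiana glauca,Tree,Reject,18,printed
invasive,Tamaricaceae,Tamarix ramosissima,Tree/shrub,Reject,21,printed
invasive,Unstated,Synthetic invasive placeholder,Unstated,Reject,16,synthetic
non_invasive,Aceraceae,Acer rubrum,Tree,Accept,10,printed
non_invasive,Anacardiaceae,Pistacia chinensis,Tree,Accept,8,printed
non_invasive,Apocynaceae,Trachelospermum asiaticum,Shrub,Accept,2,printed
non_invasive,Asteraceae,Tagetes lemmonii,Perennial dicot/shrub,Accept,4,printed
non_invasive,Caprifoliaceae,Lonicera standishii,Shrub,Accept,8,printed
non_invasive,Caryophyllaceae,Cerastium tomentosum,Perennial dicot,Accept,10,printed
non_invasive,Cistaceae,Halimium lasianthum,Shrub,Accept,2,printed
non_invasive,Cornaceae,Nyssa sylvatica,Tree,Accept,4,printed
non_invasive,Crassulaceae,Sedum palmeri,Perennial dicot,Accept,5,printed
non_invasive,Cupressaceae,Taxodium distichum,Tree,Accept,4,printed
non_invasive,Fabaceae,Acacia boormanii,Shrub,Accept,9,printed
non_invasive,Fabaceae,Cassia leptophylla,Tree,Accept,9,printed
non_invasive,Ginkgoaceae,Ginkgo biloba,Tree,Accept,4,printed
non_invasive,Goodeniaceae,Scaevola aemula,Shrub,Accept,5,printed
non_invasive,Griseliniaceae,Griselinia littoralis,Tree,Accept,4,printed
non_invasive,Hamamelidaceae,Liquidambar styraciflua,Tree,Accept,7,printed
non_invasive,Lamiaceae,Salvia greggii,Perennial dicot/shrub,Accept,3,printed
non_invasive,Lamiaceae,Salvia microphylla,Shrub,Accept,4,printed
non_invasive,Liliaceae,Dasylirion wheeleri,Shrub,Accept,7,printed
non_invasive,Liliaceae,Zephyranthes candida,Perennial monocot,Accept,6,printed
non_invasive,Myoporaceae,Myoporum parvifolium,Shrub,Accept,6,printed
non_invasive,Myrtaceae,Agonis flexuosa,Tree,Accept,7,printed
non_invasive,Oleaceae,Chionanthus retusus,Tree,Accept,5,printed
non_invasive,Oleaceae,Jasminum nudiflorum,Perennial dicot,Accept,4,printed
non_invasive,Plumbaginaceae,Ceratostigma plumbaginoides,Perennial dicot,Accept,6,printed
non_invasive,Poaceae,Bambusa multiplex,Perennial grass,Accept,10,printed
non_invasive,Poaceae,Bambusa oldhamii,Perennial grass,Accept,7,printed
non_invasive,Poaceae,Fargesia nitida,Perennial grass,Accept,3,printed
non_invasive,Poaceae,Muhlenbergia capillaris,Perennial grass,Accept,6,printed
non_invasive,Primulaceae,Cyclamen hederifolium,Perennial dicot,Accept,5,printed
non_invasive,Ranunculaceae,Helleborus argutifolius,Perennial dicot,Accept,6,printed
non_invasive,Ranunculaceae,Helleborus foetidus,Perennial dicot,Accept,6,printed
non_invasive,Rutaceae,Geijera parviflora,Tree/shrub,Accept,3,printed
non_invasive,Sapindaceae,Koelreuteria paniculata,Tree,Needs Further Evaluation,13,printed
non_invasive,Saxifragaceae,Bergenia crassifolia,Perennial dicot,Accept,5,printed
non_invasive,Scrophulariaceae,Leucophyllum frutescens,Shrub,Accept,8,printed
non_invasive,Unstated,Synthetic non-invasive placeholder,Unstated,Accept,6,synthetic
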