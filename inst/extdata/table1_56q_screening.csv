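status,family,species,common_name,growth_form,total_score,pct_answered
invasive,Apiaceae,Conium maculatum,Poison-hemlock,Biennial dicot,30,89
invasive,Apiaceae,Foeniculum vulgare,Fennel,Perennial dicot,36,93
invasive,Asteraceae,Carduus nutans,Musk thistle,Biennial dicot,35,93
invasive,Asteraceae,Cotula coronopifolia,Brassbuttons,Perennial dicot,20,80
invasive,Asteraceae,Delairea odorata,Cape-ivy,Perennial dicot,31,88
invasive,Asteraceae,Silybum marianum,Blessed milkthistle,Annual dicot,33,88
invasive,Brassicaceae,Sisymbrium irio,London rocket,Annual dicot,21,89
invasive,Chenopodiaceae,Salsola paulsenii,Barbwire Russian-thistle,Annual dicot,30,91
invasive,Dipsacaceae,Dipsacus sativus,Fuller's teasel,Biennial dicot,32,91
invasive,Euphorbiaceae,Triadica sebifera,Chinese tallowtree,Tree,31,86
invasive,Fabaceae,Acacia melanoxylon,Black acacia,Tree,33,93
invasive,Fabaceae,Genista monspessulana,French broom,Shrub,37,91
invasive,Myrtaceae,Eucalyptus camaldulensis,Red gum,Tree,30,95
invasive,Myrtaceae,Eucalyptus globulus,Tasmanian blue gum,Tree,33,91
invasive,Poaceae,Aegilops triuncialis,Barb goatgrass,Annual grass,28,82
invasive,Poaceae,Stipa capensis (= Achnatherum capense),Mediterranean steppegrass,Annual grass,21,84
invasive,Polygonaceae,Polygonum cuspidatum,Japanese knotweed,Shrub,27,84
invasive,Rosaceae,Rubus armeniacus,Himalaya blackberry,Shrub,44,98
invasive,Salviniaceae,Salvinia molesta,Giant salvinia,Perennial fern,30,93
invasive,Scrophulariaceae,Linaria genistifolia ssp. dalmatica,Dalmatian toadflax,Perennial dicot,32,89
invasive,Tamaricaceae,Tamarix parviflora,Smallflower tamarisk,Tree/shrub,33,95
non_invasive,Fabaceae,Calliandra tweedii,Brazilian flamebush,Shrub,9,86
non_invasive,Campanulaceae,Campanula poscharskyana,Serbian bellflower,Perennial dicot,11,91
non_invasive,Bignoniaceae,Chilopsis linearis,Desert willow,Tree,11,91
non_invasive,Cupressaceae,Cupressus arizonica,Arizona cypress,Tree,11,89
non_invasive,Aizoaceae,Delosperma cooperi,Trailing iceplant,Perennial dicot,14,88
non_invasive,Asteraceae,Euryops pectinatus,Yellow bush daisy,Shrub,13,86
non_invasive,Oleaceae,Forsythia x intermedia,Forsythia,Shrub,5,95
non_invasive,Poaceae,Helictotrichon sempervirens,Blue oatgrass,Perennial grass,6,89
non_invasive,Rosaceae,Kerria japonica,Japanese rose,Shrub,10,88
non_invasive,Lauraceae,Laurus nobilis,Sweet bay,Tree,7,88
non_invasive,Agavaceae,Phormium tenax,New Zealand flax,Perennial monocot,11,89
non_invasive,Buxaceae,Sarcococca hookeriana var. humilis,Sweet box,Shrub,7,88
non_invasive,Lamiaceae,Teucrium chamaedrys,Wall germander,Perennial dicot,10,89
non_invasive,Caprifoliaceae,Viburnum awabuki,Sweet viburnum,Tree,9,88
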