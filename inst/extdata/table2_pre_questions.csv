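id,number,text,fisher_p,significant,pct_answered_invasive,pct_answered_noninvasive,points_yes,points_no
q01,1,"Has the species become naturalized where it is not native?","<0.0001",TRUE,100,100,1,0
q02,2,"Is the species noted as being invasive elsewhere in the US or world?","<0.0001",TRUE,100,100,2,0
q03,3,"Is the species noted as being invasive elsewhere in the US or world in a similar climate?","<0.0001",TRUE,100,100,3,0
q04,4,"Are other species of the same genus invasive in other areas with a similar climate?","<0.0001",TRUE,100,100,1,0
q05,5,"Is the species found predominately in a climate that matches those within the region of introduction?","",FALSE,96,100,2,0
q06,6,"Does this plant displace native plants and dominate the plant community in areas where it has invaded? Does this plant overtop and/or smother surrounding vegetation?","<0.0001",TRUE,100,100,1,0
q07,7,"Is the plant noted as being highly flammable and/or promotes fire and/or changes fire regimes?","<0.0001",TRUE,79,97,1,0
q08,8,"Is the plant a health risk to humans or animals/fish? (Toxic tendencies) Has the species been noted as impacting grazing systems?","0.0001",TRUE,100,100,1,0
q09,9,"Does the plant produce impenetrable thickets, blocking or slowing movement?","0.0002",TRUE,93,100,1,0
q10,10,"Does this plant reproduce vegetatively via root sprouts/suckers or stem/trunk sprouts/coppicing?","0.0314",TRUE,98,100,1,0
q11,11,"Are fragments from this plant capable of producing new plants?","0.0002",TRUE,100,100,1,0
q12,12,"Does this species produce viable seed?","0.0001",TRUE,100,100,1,0
q13,13,"Does this plant produce copious viable seeds each year (>1000)?","<0.0001",TRUE,86,78,1,0
q14,14,"Does this plant produce seeds that germinate quickly (<2 months)?","0.1296",FALSE,75,68,1,0
q15,15,"Does this plant have a short juvenile period? Does it produce seed within first three years (herbaceous) or first five years (woody)?","0.0078",TRUE,89,54,1,0
q16,16,"Does this plant have a long flowering period with seeds produced for >3 months each year?","0.2320",FALSE,86,86,1,0
q17,17,"Are this plant's propagules dispersed by mammals/insects or birds or via domestic animals?","<0.0001",TRUE,100,97,1,0
q18,18,"Are this plant's propagules dispersed by wind or water?","<0.0001",TRUE,98,97,1,0
q19,19,"Are this plant's propagules dispersed via agriculture, contaminated seed, farm equipment, vehicles or boats, or clothing/shoes?","<0.0001",TRUE,100,94,1,0
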