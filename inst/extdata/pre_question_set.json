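{
  "name": "PlantRight PRE",
  "version": "2015",
  "questions": [
    {
      "id": "q01",
      "text": "Has the species become naturalized where it is not native?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q02",
      "text": "Is the species noted as being invasive elsewhere in the US or world?",
      "points_yes": 2,
      "points_no": 0
    },
    {
      "id": "q03",
      "text": "Is the species noted as being invasive elsewhere in the US or world in a similar climate?",
      "points_yes": 3,
      "points_no": 0
    },
    {
      "id": "q04",
      "text": "Are other species of the same genus invasive in other areas with a similar climate?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q05",
      "text": "Is the species found predominately in a climate that matches those within the region of introduction?",
      "points_yes": 2,
      "points_no": 0
    },
    {
      "id": "q06",
      "text": "Does this plant displace native plants and dominate the plant community in areas where it has invaded? Does this plant overtop and/or smother surrounding vegetation?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q07",
      "text": "Is the plant noted as being highly flammable and/or promotes fire and/or changes fire regimes?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q08",
      "text": "Is the plant a health risk to humans or animals/fish? (Toxic tendencies) Has the species been noted as impacting grazing systems?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q09",
      "text": "Does the plant produce impenetrable thickets, blocking or slowing movement?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q10",
      "text": "Does this plant reproduce vegetatively via root sprouts/suckers or stem/trunk sprouts/coppicing?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q11",
      "text": "Are fragments from this plant capable of producing new plants?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q12",
      "text": "Does this species produce viable seed?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q13",
      "text": "Does this plant produce copious viable seeds each year (>1000)?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q14",
      "text": "Does this plant produce seeds that germinate quickly (<2 months)?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q15",
      "text": "Does this plant have a short juvenile period? Does it produce seed within first three years (herbaceous) or first five years (woody)?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q16",
      "text": "Does this plant have a long flowering period with seeds produced for >3 months each year?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q17",
      "text": "Are this plant's propagules dispersed by mammals/insects or birds or via domestic animals?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q18",
      "text": "Are this plant's propagules dispersed by wind or water?",
      "points_yes": 1,
      "points_no": 0
    },
    {
      "id": "q19",
      "text": "Are this plant's propagules dispersed via agriculture, contaminated seed, farm equipment, vehicles or boats, or clothing/shoes?",
      "points_yes": 1,
      "points_no": 0
    }
  ]
}
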