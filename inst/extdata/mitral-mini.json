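{
  "graphs": [
    {
      "nodes": [
        {
          "id": "http://purl.obolibrary.org/obo/CL_0000540",
          "lbl": "neuron",
          "type": "CLASS",
          "meta": {
            "definition": {"val": "The basic cellular unit of nervous tissue."},
            "basicPropertyValues": [
              {"pred": "http://www.geneontology.org/formats/oboInOwl#creation_date", "val": "2010-05-20T00:00:00Z"}
            ]
          }
        },
        {
          "id": "http://purl.obolibrary.org/obo/CL_0000099",
          "lbl": "interneuron",
          "type": "CLASS",
          "meta": {
            "definition": {"val": "Most generally, any neuron which connects two or more other neurons."},
            "basicPropertyValues": [
              {"pred": "http://www.geneontology.org/formats/oboInOwl#creation_date", "val": "2011-03-14T00:00:00Z"}
            ]
          }
        },
        {
          "id": "http://purl.obolibrary.org/obo/UBERON_0004186",
          "lbl": "olfactory bulb mitral cell layer",
          "type": "CLASS",
          "meta": {
            "definition": {"val": "A layer of the olfactory bulb composed of mitral cell bodies."}
          }
        },
        {
          "id": "http://purl.obolibrary.org/obo/CL_1001502",
          "lbl": "mitral cell",
          "type": "CLASS",
          "meta": {
            "definition": {"val": "The large glutaminergic nerve cells whose dendrites synapse with axons of the olfactory receptor neurons in the glomerular layer of the olfactory bulb, and whose axons pass centrally in the olfactory tract to the olfactory cortex."},
            "basicPropertyValues": [
              {"pred": "http://www.geneontology.org/formats/oboInOwl#creation_date", "val": "2023-01-10T00:00:00Z"}
            ]
          }
        },
        {
          "id": "http://purl.obolibrary.org/obo/CL_0000548",
          "lbl": "animal cell",
          "type": "CLASS"
        },
        {
          "id": "http://purl.obolibrary.org/obo/CL_9999999",
          "lbl": "retired cell",
          "type": "CLASS",
          "meta": {"deprecated": true}
        },
        {
          "id": "http://purl.obolibrary.org/obo/RO_0002100",
          "lbl": "has soma location",
          "type": "PROPERTY"
        }
      ],
      "edges": [
        {"sub": "http://purl.obolibrary.org/obo/CL_0000099", "pred": "is_a", "obj": "http://purl.obolibrary.org/obo/CL_0000540"},
        {"sub": "http://purl.obolibrary.org/obo/CL_0000540", "pred": "is_a", "obj": "http://purl.obolibrary.org/obo/CL_0000548"},
        {"sub": "http://purl.obolibrary.org/obo/CL_1001502", "pred": "is_a", "obj": "http://purl.obolibrary.org/obo/CL_0000099"},
        {"sub": "http://purl.obolibrary.org/obo/CL_1001502", "pred": "http://purl.obolibrary.org/obo/RO_0002100", "obj": "http://purl.obolibrary.org/obo/UBERON_0004186"},
        {"sub": "http://purl.obolibrary.org/obo/CL_1001502", "pred": "is_a", "obj": "http://purl.obolibrary.org/obo/CL_0000000"}
      ]
    }
  ]
}
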