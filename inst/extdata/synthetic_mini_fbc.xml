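<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic three-compartment mini model (hand-written test fixture,
     not derived from any published reconstruction).  Exercises the
     SBML Level 3 + FBC subset: parameters as flux bounds (including an
     explicit INF upper bound), gene product associations with nested
     and/or, an active objective, and a cytosol/periplasm/extracellular
     compartment chain. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="synthetic_mini" name="synthetic mini model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" name="cytosol" constant="true"/>
      <compartment id="p" name="periplasm" constant="true"/>
      <compartment id="e" name="extracellular" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" name="D-glucose" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="glc_p" name="D-glucose" compartment="p" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="glc_c" name="D-glucose" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="pyr_c" name="pyruvate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="kiv_c" name="2-ketoisovalerate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="lb_0" value="0" constant="true"/>
      <parameter id="ub_1000" value="1000" constant="true"/>
      <parameter id="ub_inf" value="INF" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_glc" name="glucose exchange" reversible="true" fast="false" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="GLCtex" name="glucose diffusion e to p" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_p" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="GLCtpp" name="glucose transport p to c" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="glc_p" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="GLY" name="glycolysis lump" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="glc_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pyr_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_b0001"/>
              <fbc:geneProductRef fbc:geneProduct="G_b0002"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_b0003"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="KIVS" name="2-KIV synthesis lump" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="pyr_c" stoichiometry="2" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="kiv_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_b0002"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="BIOMASS_synth" name="biomass drain" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="pyr_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS_synth" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_b0001" fbc:label="gapA"/>
      <fbc:geneProduct fbc:id="G_b0002" fbc:label="alsS"/>
      <fbc:geneProduct fbc:id="G_b0003" fbc:label="pykF"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
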