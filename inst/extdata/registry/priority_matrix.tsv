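name	omop	openehr	fhir	cdisc
MetadataID	metadata_concept_id	versionID	Meta.versionID	ODM/Study/MetaDataVersion
MetadataDate	metadata_date		DataRequirement	ODM/AsOfDatetime
AffiliateDatasetID	source_description_reference	resource_description_item:original_resource	DataRequirement.Profile	def:Origin
MetadataVersion	metadata_concept_id	versionID	Meta.versionID	ODM/Study/MetaDataVersion
ReferenceData		resource_description:references	RelatedArtifact	def:LeafElement
ReferenceMetadata
DataLifecycleState		resource_description:lifecycle_state		def:AnnotatedCRF
UsageLicense/Copyright		resource_description:copyright
UsageContext		resource_description_item:use	UsageContext	StudyDescription
SourceSystemName	cdm_source_name	resource_description:parent_resource	Meta.profile	def:Origin
SourceSystemVersion
SourceInformation	source_description	resource_description_item:purpose	DataRequirement.type	def:Origin
SourceOriginalContributor	cdm_holder	resource_description:original_author|resource_description:original_publisher	Contributor	def:Origin
VestingPeriod
ConsentType
ConsentValidation
ConsentVerification
ConsentModule
DataItemLanguage		resource_description_item:language
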